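# Dynamic viscosities of mAb solutions measured with rotational rheometry
# at 297 K (cone-plate, shear rate 1000 1/s). Columns: mass concentration
# [mg/mL], dynamic viscosity [mPa.s], sterile-filtered flag.
concentration	viscosity	filtered
98	2.7	TRUE
126	5.5	TRUE
132	5.7	TRUE
216	36.5	TRUE
50	2.1	FALSE
192	19.1	FALSE
199	19.3	FALSE
213	23.2	FALSE
216	32.5	FALSE
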