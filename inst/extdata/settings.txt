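# Pipeline settings. Missing keys take their defaults; the legacy labels
# E_value, Orthologs_count, Min_UP_length and Max_UP_length are accepted.
evalue_cutoff = 1e-3
min_orthologs = 4
min_up_length = 50
max_up_length = 350
# tu_gap_threshold follows min_up_length unless set here
representative_mode = gene-self
window_mode = fixed-window
min_members = 2
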