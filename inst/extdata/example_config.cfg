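# Example fishprobes configuration: every unset key takes its documented
# default (see write_config() for the full commented list).
min_bits=200
min_unique_len=4000
max_gap=500
amplicon_min=1000
amplicon_max=10000
forbidden_sites=ATCGAT
site_mode=enforce
primer_tm_opt=60
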