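24f4066dcb4df9e47e7184b718c1dd59 cnv_events.tsv
ab2de38adc14fbc90cdf069fdbd16c33 snv_events.tsv
0c3770d09a44bd81512540d664c8eda6 gene_modes.tsv
1aeb8b54d0e8d7e18ddfd8f1ea7b0418 samples.tsv
0fd400340b6b7f75fb163b5e2fb3cf9c lowpass_extras.tsv
5159e90a4cd6809651e55062b18f8575 meta.tsv
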