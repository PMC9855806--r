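"entry_id","chain_id","ec_numbers","go_terms","keywords","description"
"SYNOB001","A","","oxygen binding [GO:0019825]","oxygen storage","synthetic oxygen-binding globin"
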