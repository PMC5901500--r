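snp_id	expressed
rs10046	TRUE
rs934634	TRUE
rs9467075	TRUE
rs600753	TRUE
rs555879	FALSE
rs2143340	FALSE
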