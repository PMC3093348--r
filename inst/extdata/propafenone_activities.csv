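ligand_id,pIC50,HAC,logP
GPV005,6.22,27,4.38
GPV019,6.21,33,5.15
GPV062,7.24,34,4.15
GPV186,6.19,26,5.54
GPV366,5.78,33,4.94
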