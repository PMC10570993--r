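model_id,nup_name,terminus,copy,z,r,alpha,subcomplex,unit
synthetic,SynNup,C,1,25,53.7,0,CR,nm
synthetic,SynNup,C,2,-25,53.7,0,NR,nm
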