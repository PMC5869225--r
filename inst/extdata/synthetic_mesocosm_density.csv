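site_id,density
site01,43.3236749790842
site02,44.3369313050527
site08,7.82733017432038
site09,31.5931492132833
site10,33.7804476736812
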