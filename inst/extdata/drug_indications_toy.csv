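drug_id,ingredients,indications
prozac,fluoxetine,depression
zoloft,sertraline,depression
celexa,citalopram,depression
lexapro,escitalopram,depression
effexor,venlafaxine,depression
elavil,amitriptyline,depression;migraine
wellbutrin,bupropion,depression;smoking_cessation
advil,ibuprofen,pain
lyrica,pregabalin,neuropathic_pain;anxiety
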