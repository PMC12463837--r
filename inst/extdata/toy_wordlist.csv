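variety,family,water,fire,stone,tree,eye,two
Alpha,F1,maji,moto,jiwe,mti,jicho,mbili
Beta,F1,madzi,moto,dziwe,muti,dzitso,wili
Gamma,F2,pii,kima,?,keno,konyu,are
Delta,F2,piyo,kimo,soit,,kong,aree
Epsilon,F3,biyyo,ibidda,dhagaa,muka,ija,lama
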