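compound,threshold_ugL,matrix
Isoamyl acetate,30,wine
Ethyl hexanoate,14,wine
Ethyl heptanoate,220,wine
Methyl octanoate,200,wine
Ethyl octanoate,5,wine
Isoamyl hexanoate,1000,wine
Ethyl nonanoate,1300,wine
Linalool,25.2,wine
1-Hexanol,8000,wine
1-Octanol,110,wine
Caryophyllene,64,wine
1-Nonanol,600,wine
alpha-Terpineol,250,wine
TDN,2,wine
Methyl salicylate,40,wine
2-Phenylethyl acetate,250,wine
beta-Damascenone,4.5,wine
Ethyl hydrocinnamate,1.6,wine
beta-Ionone,0.09,wine
1-Dodecanol,1000,wine
Ethyl hexadecanoate,1500,wine
p-Cymene,11.4,wine
Terpinolene,200,wine
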