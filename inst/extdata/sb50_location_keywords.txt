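# San Francisco Bay Area location keywords for the prospective joint filter.
sf
sanfrancisco
san
francisco
sanfran
prayforsanfrancisco
bayarea
sfbayarea
bay
sanfranciscobay
northerncalifornia
norcal
california
ca
sfgh
zfgh
thegeneral
general
goldengatebridge
goldengate
bridge
baybridge
bart
caltrain
muni
cablecar
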