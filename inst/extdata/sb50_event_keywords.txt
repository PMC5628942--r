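# Generic event keywords for the prospective joint event+location filter.
breaking
news
breakingnews
cnn
pray
crash
shot
shooting
stab
stabbed
stabbing
fall
dead
died
accident
earthquake
flood
victim
victims
fatality
fatalities
attack
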