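retina
retinal
retinitis
photoreceptor
rod
cone
blindness
ciliopathy
Bardet-Biedl
macular
degeneration
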