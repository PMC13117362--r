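term	synonym
loss	deficit
difficulty	trouble
assistance	help
episodes	events
reduced	decreased
impaired	diminished
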