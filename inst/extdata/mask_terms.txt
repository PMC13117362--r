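alzheimer's disease
alzheimers disease
alzheimer disease
alzheimer
dementia
mild cognitive impairment
mci
cognitive decline
cognitive impairment
memory disorder
neurodegenerative disease
senile
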