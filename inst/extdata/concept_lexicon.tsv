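phrase	concept_id	is_diagnostic	domain
memory loss	C0027498	0	cognition
memory lapses	C0751295	0	cognition
disorientation	C0233407	0	cognition
confusion	C0009676	0	cognition
word finding difficulty	C0454643	0	cognition
poor recall	C0589095	0	cognition
impaired judgment	C0233538	0	cognition
reduced attention	C0233417	0	cognition
repetitive questioning	C0871416	0	cognition
misplacing objects	C0751297	0	cognition
getting lost	C0751298	0	cognition
forgetfulness	C0542476	0	cognition
slowed thinking	C0233565	0	cognition
naming difficulty	C0027383	0	cognition
comprehension difficulty	C0542377	0	cognition
tangential speech	C0233655	0	cognition
independent living	C0682343	0	independence
lives alone	C0562385	0	independence
drives independently	C0562386	0	independence
manages finances	C0562387	0	independence
manages medications	C0562388	0	independence
prepares meals	C0562389	0	independence
shops independently	C0562390	0	independence
walks unaided	C0562391	0	independence
independent dressing	C0562392	0	independence
independent bathing	C0562393	0	independence
attends appointments	C0562394	0	independence
hobbies maintained	C0562395	0	independence
socially active	C0562396	0	independence
oriented fully	C0562397	0	independence
caregiver support	C0085537	0	care
needs supervision	C0558054	0	care
assistance with dressing	C0558055	0	care
assistance with bathing	C0558056	0	care
feeding assistance	C0558057	0	care
wheelchair dependent	C0558058	0	care
wandering episodes	C0558059	0	care
agitation episodes	C0085631	0	care
sundowning behavior	C0558060	0	care
incontinence episodes	C0021167	0	care
fall risk	C0558061	0	care
swallowing difficulty	C0011168	0	care
weight loss	C1262477	0	care
sleep disturbance	C0037317	0	care
caregiver burnout	C0558062	0	care
day program enrollment	C0558063	0	care
home health aide	C0558064	0	care
nursing placement	C0558065	0	care
total care required	C0558066	0	care
behavioral outbursts	C0558067	0	care
alzheimer disease	C0002395	1	diagnostic
alzheimers disease	C0002395	1	diagnostic
dementia	C0011265	1	diagnostic
mild cognitive impairment	C1270972	1	diagnostic
cognitive decline	C0234985	1	diagnostic
senile dementia	C0011269	1	diagnostic
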