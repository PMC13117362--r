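short	expansion
pt	patient
pts	patients
c/o	complains of
hx	history
dx	diagnosis
rx	prescription
meds	medications
appt	appointment
w/	with
s/p	status post
yo	year old
b/l	bilateral
sob	shortness of breath
adl	activities of daily living
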