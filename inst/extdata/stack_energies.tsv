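# RNA/RNA nearest-neighbor stack free energies, kcal/mol at 37 C.
# Watson-Crick stacks follow the Turner-style unified parameter set.
# Rows give pair1 followed by pair2 along the top strand 5'->3'; a pair "XY"
# means top-strand base X paired with bottom-strand base Y. GU-wobble-containing
# stacks use a simplified uniform -0.50 kcal/mol so every stack is stabilizing;
# edit this file to change the energy semantics of the deltaG filter.
pair1	pair2	dg
AU	AU	-0.93
AU	UA	-1.10
UA	AU	-1.33
UA	UA	-0.93
CG	UA	-2.08
AU	GC	-2.08
CG	AU	-2.11
UA	GC	-2.11
GC	UA	-2.24
AU	CG	-2.24
GC	AU	-2.35
UA	CG	-2.35
CG	GC	-2.36
GC	CG	-3.42
GC	GC	-3.26
CG	CG	-3.26
GU	AU	-0.50
GU	UA	-0.50
GU	CG	-0.50
GU	GC	-0.50
GU	GU	-0.50
GU	UG	-0.50
UG	AU	-0.50
UG	UA	-0.50
UG	CG	-0.50
UG	GC	-0.50
UG	GU	-0.50
UG	UG	-0.50
AU	GU	-0.50
AU	UG	-0.50
UA	GU	-0.50
UA	UG	-0.50
CG	GU	-0.50
CG	UG	-0.50
GC	GU	-0.50
GC	UG	-0.50
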