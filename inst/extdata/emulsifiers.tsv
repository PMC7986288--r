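emulsifier	e_number	manufacturer
Sodium carboxymethylcellulose (CMC)	466	Sigma
Polysorbate 80 (P80)	433	Sigma
Soy lecithin	322	Modernist Pantry LLC
Sunflower lecithin	322	Swanson Health Products
Maltodextrin	1400	Bulk Supplements
Propylene glycol alginate	405	Modernist Pantry LLC
Iota carrageenan	407	Modernist Pantry
Kappa carrageenan	407	Modernist Pantry
Lambda carrageenan	407	Modernist Pantry LLC
Xantham gum	415	Judee's Gluten Free
Gum arabic	414	Frontier Co-op
Guar gum	412	Now Foods
Locust bean gum	410	Modernist Pantry LLC
Agar agar	406	ScrapCooking
DATEM	472e	Modernist Pantry LLC
Hydroxypropyl methyl cellulose (HPMC)	464	Sigma
Sorbitan monostearate	491	Sigma
Mono- and diglycerides	471	Modernist Pantry LLC
Glyceryl stearate	471	Lonza Inc
Glyceryl oleate	471	Lonza Inc
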