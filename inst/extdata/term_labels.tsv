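key	sbo_label	sbo_id
generic_biochemical	biochemical reaction	176
exchange	exchange reaction	627
demand	demand reaction	628
sink	sink reaction	632
biomass	biomass production	629
transport_generic	transport reaction	655
transport_passive	passive transport	658
transport_active_atp	active transport	657
transport_active_pep	active transport	657
transport_symport	symporter-mediated transport	659
transport_antiport	antiporter-mediated transport	660
species	simple chemical	247
macromolecule	macromolecule	245
gene	gene	243
modifier_enzymatic	enzymatic catalyst	460
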