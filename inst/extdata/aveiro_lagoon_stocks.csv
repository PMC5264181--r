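element,species,compartment,stock_mg,status,provenance
C,Spartina maritima,plant,2326,measured,Ria de Aveiro field survey
C,Juncus maritimus,plant,17368,measured,Ria de Aveiro field survey
C,Halimione portulacoides,plant,13118,inferred,Tagus estuary mid marsh (reference)
C,Sarcocornia perennis,plant,1946,inferred,Tagus estuary mid marsh (reference)
C,Bolboschoenus maritimus,plant,948,inferred,Mondego estuary marsh (reference)
C,Spartina maritima,sediment,22188,measured,Ria de Aveiro field survey
C,Juncus maritimus,sediment,69017,measured,Ria de Aveiro field survey
C,Halimione portulacoides,sediment,104102,inferred,Tagus estuary mid marsh (reference)
C,Sarcocornia perennis,sediment,14578,inferred,Tagus estuary mid marsh (reference)
C,Bolboschoenus maritimus,sediment,6461,inferred,Mondego estuary marsh (reference)
N,Spartina maritima,plant,84,measured,Ria de Aveiro field survey
N,Juncus maritimus,plant,619,measured,Ria de Aveiro field survey
N,Halimione portulacoides,plant,678,inferred,Tagus estuary mid marsh (reference)
N,Sarcocornia perennis,plant,78,inferred,Tagus estuary mid marsh (reference)
N,Bolboschoenus maritimus,plant,30,inferred,Mondego estuary marsh (reference)
N,Spartina maritima,sediment,1576,measured,Ria de Aveiro field survey
N,Juncus maritimus,sediment,5385,measured,Ria de Aveiro field survey
N,Halimione portulacoides,sediment,25442,inferred,Tagus estuary mid marsh (reference)
N,Sarcocornia perennis,sediment,3590,inferred,Tagus estuary mid marsh (reference)
N,Bolboschoenus maritimus,sediment,619,inferred,Mondego estuary marsh (reference)
P,Spartina maritima,plant,13,measured,Ria de Aveiro field survey
P,Juncus maritimus,plant,110,measured,Ria de Aveiro field survey
P,Halimione portulacoides,plant,349,inferred,Tagus estuary mid marsh (reference)
P,Sarcocornia perennis,plant,33,inferred,Tagus estuary mid marsh (reference)
P,Bolboschoenus maritimus,plant,5,inferred,Mondego estuary marsh (reference)
P,Spartina maritima,sediment,497,measured,Ria de Aveiro field survey
P,Juncus maritimus,sediment,1320,measured,Ria de Aveiro field survey
P,Halimione portulacoides,sediment,4559,inferred,Tagus estuary mid marsh (reference)
P,Sarcocornia perennis,sediment,516,inferred,Tagus estuary mid marsh (reference)
P,Bolboschoenus maritimus,sediment,160,inferred,Mondego estuary marsh (reference)
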