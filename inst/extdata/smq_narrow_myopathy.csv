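pt_name,meddra_code,scope
Rhabdomyolysis,10039020,narrow
Myopathy,10028641,narrow
Toxic myopathy,10044004,narrow
Necrotising myositis,10074688,narrow
Necrotizing myositis,10074688,narrow
Muscle necrosis,10028310,narrow
Myoglobinuria,10028629,narrow
Myoglobin blood increased,10028622,narrow
Myoglobin blood present,10028623,narrow
Myoglobin urine present,10028631,narrow
Myoglobinaemia,10056840,narrow
Immune-mediated necrotising myopathy,10083750,narrow
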