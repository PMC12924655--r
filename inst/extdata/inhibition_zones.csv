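strain,diameter_mm,subculture
Micrococcus luteus strain T-18,15,Positive
Streptococcus pyogenes strain FF22,14,Positive
S. anginosus strain T-29,13,Negative
S. pyogenes strain 70-679,15,Negative
S. uberis strain T-6,14,Negative
S. pyogenes strain 71-679,15,Positive
S. pyogenes strain 71-698,16,Positive
S. pyogenes strain W-1,14,Negative
S. equisimilis strain T-148,15,Negative
Enterococcus faecalis strain 96,16,Positive
E. faecalis strain 97,13,Negative
E. faecalis strain 98,12,Positive
S. dysgalactiae strain 60,14,Positive
S. dysgalactiae strain 61,15,Positive
S. dysgalactiae strain 62,16,Positive
S. agalactiae strain 76,16,Positive
S. agalactiae strain 77,14,Positive
S. agalactiae strain 78,15,Positive
Enterococcus faecalis strain E024,14,Positive
E. faecalis strain C2,13,Negative
E. faecalis strain K13b,13,Positive
Enterococcus faecium strain TE1,12,Positive
E. faecium strain A10,14,Negative
E. faecium strain 5A9,13,Positive
E. faecalis strain JM95,13,Positive
E. faecalis strain JM101,12,Positive
E. faecalis strain JM112,13,Positive
Salmonella enterica subsp. enterica serovar Typhi isolate 1,15,Positive
Salmonella enterica subsp. enterica serovar Typhi isolate 2,13,Negative
Escherichia coli O157 isolate 1,14,Positive
Enteropathogenic E. coli isolate 1,12,Positive
Enteroaggregative E. coli isolate 1,12,Positive
Campylobacter jejuni isolate 1,13,Positive
Listeria monocytogenes isolate 1,14,Negative
Methicillin-resistant Staphylococcus aureus (MRSA) isolate 1,16,Positive
Methicillin-resistant Staphylococcus aureus (MRSA) isolate 2,15,Negative
Methicillin-resistant Staphylococcus aureus (MRSA) isolate 3,14,Positive
Shigella dysenteriae isolate 1,14,Positive
Shigella flexneri isolate 1,13,Positive
Vibrio cholerae isolate 1,13,Negative
Vibrio parahaemolyticus isolate 1,13,Negative
Carbapenem-resistant Pseudomonas aeruginosa (CRPA) isolate 1,12,Negative
Carbapenem-resistant Pseudomonas aeruginosa (CRPA) isolate 2,13,Negative
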