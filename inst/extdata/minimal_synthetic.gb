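LOCUS       MINI01 60 bp    DNA     circular   UNA
DEFINITION  Minimal synthetic fixture: one CDS and one control region.
FEATURES             Location/Qualifiers
     source          1..60
     CDS             1..30
                     /gene="CDS1"
     D-loop          41..60
                     /note="control region"
ORIGIN
        1 atgaaacccg ggtttacgta cgtacgttaa gcgcgcgcgc acacacacac gtgtgtgtgt
//
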