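# Default allerquant registry: milk and egg allergen markers for baked
# (cookie) matrices.
#
# Notes:
#  * protein rel_abundance values are literature-derived defaults (mass
#    fraction of the protein within the ingredient's total protein); they are
#    not instrument constants and may be edited to match the materials in use.
#  * NIP precursor recorded as 671.8; a 671.6 variant circulates in some
#    chromatogram annotations.
#  * Transitions for YLG, VLV, GGL and NIG are computed defaults
#    (monoisotopic doubly protonated precursor, singly charged y-ion
#    product), not instrument-optimized values; replace after tuning.
#  * Marker mw_avg is computed from the sequence at load time unless
#    overridden here.
schema: allerquant-registry/1
ingredients:
  - name: skim milk powder
    allergen: milk
    protein_fraction: 0.3539
  - name: whole egg powder
    allergen: egg
    protein_fraction: 0.4805
  - name: MoniQA SMP reference material
    allergen: milk
    protein_fraction: 0.354
proteins:
  - name: alpha-S1-casein
    allergen: milk
    ingredient: skim milk powder
    uniprot_hint: P02662
    mw_avg: 23615
    rel_abundance: 0.32
  - name: beta-lactoglobulin
    allergen: milk
    ingredient: skim milk powder
    uniprot_hint: P02754
    mw_avg: 18281
    rel_abundance: 0.10
  - name: ovalbumin
    allergen: egg
    ingredient: whole egg powder
    uniprot_hint: P01012
    mw_avg: 42750
    rel_abundance: 0.30
  - name: vitellogenin-2
    allergen: egg
    ingredient: whole egg powder
    uniprot_hint: P02845
    mw_avg: 204000
    rel_abundance: 0.11
markers:
  - code: FFV
    sequence: FFVAPFPEVFGK
    protein: alpha-S1-casein
    transitions:
      - {q1_mz: 692.9, q3_mz: 991.4, role: quantifier}
      - {q1_mz: 692.9, q3_mz: 920.3, role: qualifier}
  - code: YLG
    sequence: YLGYLEQLLR
    protein: alpha-S1-casein
    transitions:
      - {q1_mz: 634.4, q3_mz: 991.6, role: quantifier}
      - {q1_mz: 634.4, q3_mz: 771.5, role: qualifier}
  - code: TPE
    sequence: TPEVDDEALEK
    protein: beta-lactoglobulin
    transitions:
      - {q1_mz: 623.3, q3_mz: 572.5, role: quantifier}
      - {q1_mz: 623.3, q3_mz: 819.1, role: qualifier}
  - code: VLV
    sequence: VLVLDTDYK
    protein: beta-lactoglobulin
    transitions:
      - {q1_mz: 533.3, q3_mz: 853.4, role: quantifier}
      - {q1_mz: 533.3, q3_mz: 641.3, role: qualifier}
  - code: ISQ
    sequence: ISQAVHAAHAEINEAGR
    protein: ovalbumin
    transitions:
      - {q1_mz: 592.1, q3_mz: 858.9, role: quantifier}
      - {q1_mz: 592.1, q3_mz: 778.5, role: qualifier}
  - code: GGL
    sequence: GGLEPINFQTAADQAR
    protein: ovalbumin
    transitions:
      - {q1_mz: 844.4, q3_mz: 860.4, role: quantifier}
      - {q1_mz: 844.4, q3_mz: 1121.5, role: qualifier}
  - code: NIP
    sequence: NIPFAEYPTYK
    protein: vitellogenin-2
    transitions:
      - {q1_mz: 671.8, q3_mz: 557.9, role: quantifier}
      - {q1_mz: 671.8, q3_mz: 1114.9, role: qualifier}
  - code: NIG
    sequence: NIGELGVEK
    protein: vitellogenin-2
    transitions:
      - {q1_mz: 479.8, q3_mz: 731.4, role: quantifier}
      - {q1_mz: 479.8, q3_mz: 545.3, role: qualifier}
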