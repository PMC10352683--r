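# Default 10-gene HNSCC panel.
# carcinogenSigns are listed in carcinogen order (alcohol, smoking):
# +1 = the carcinogen upregulates the gene, -1 = downregulates, 0 = no effect.
# phenotypeEffects apply in the gene's positive-mutation direction
# (downregulation for suppressors, upregulation for oncogenes).
carcinogens:
  - alcohol
  - smoking
mutationThreshold: 0.1
upsilon: 4
incrementMagnitude: 1.0e-6
ageWeight: 1.0e-7
genes:
  - name: TP53
    type: suppressor
    carcinogenSigns: [1, -1]
    phenotypeEffects: {proliferation: up, apoptosis: down, quiescence: down}
    activates: {TP21: up, TP16: up, RB: up}
    relatedToAll: true
  - name: TP73
    type: suppressor
    carcinogenSigns: [0, 0]
    phenotypeEffects: {apoptosis: down}
  - name: RB
    type: suppressor
    carcinogenSigns: [0, -1]
    phenotypeEffects: {proliferation: up, differentiation: up, quiescence: down}
    activates: {TP53: up, CCDN1: up}
  - name: TP21
    type: suppressor
    carcinogenSigns: [1, -1]
    phenotypeEffects: {proliferation: up}
  - name: TP16
    type: suppressor
    carcinogenSigns: [1, 0]
    phenotypeEffects: {proliferation: up}
  - name: EGFR
    type: oncogene
    carcinogenSigns: [1, 1]
    phenotypeEffects: {proliferation: up}
  - name: CCDN1
    type: oncogene
    carcinogenSigns: [1, 1]
    phenotypeEffects: {apoptosis: down}
    activates: {TP21: up}
  - name: MYC
    type: oncogene
    carcinogenSigns: [0, 1]
    phenotypeEffects: {proliferation: up, differentiation: up, apoptosis: down}
    activates: {TP21: down, RAS: up}
  - name: PIK3CA
    type: oncogene
    carcinogenSigns: [0, 1]
    phenotypeEffects: {apoptosis: down}
  - name: RAS
    type: oncogene
    carcinogenSigns: [1, 1]
    phenotypeEffects: {proliferation: up, differentiation: up, apoptosis: down}
    activates: {CCDN1: up, MYC: up}
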