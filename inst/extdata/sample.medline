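PMID- 10001
TI  - Accuracy of the clinical examination for diagnosing heart failure in
      adults presenting with dyspnea.
AB  - We measured the sensitivity and specificity of the third heart sound
      for the diagnosis of congestive heart failure.
MH  - *Heart Failure/diagnosis
MH  - Physical Examination
MH  - Sensitivity and Specificity
PT  - Journal Article
DP  - 2000 Mar
JT  - Test Journal of Medicine

PMID- 10002
TI  - Magnetic resonance imaging of the knee.
AB  - Imaging findings in meniscal tears.
MH  - Magnetic Resonance Imaging/*methods
MH  - Knee Injuries/diagnosis/pathology
PT  - Journal Article
PT  - Comparative Study
DP  - 2000

PMID- 10003
TI  - Symptoms and signs in acute appendicitis: a prospective study.
MH  - Appendicitis/*diagnosis
MH  - Medical History Taking
PT  - Clinical Trial
DP  - 1999 Dec
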