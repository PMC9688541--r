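# Packaged cohort tables

Machine-readable copies of the published per-patient tables of the
18-patient audiovisual-oddball P300 study that this package re-analyses:

- `doc_cohort_patients.csv` — demographics, etiology, diagnoses before the
  experiment and at the three-month follow-up, and CRS-R totals with the six
  subscores (auditory, visual, motor, oromotor, communication, arousal) at
  both assessments. Transcription note: patient P11's printed
  before-experiment total (12) disagrees with the sum of its printed
  subscores (1-2-5-1-0-2 = 11); this file stores 11 so that every row
  satisfies the total-equals-subscore-sum invariant enforced by
  `load_patient_table()`. No analysed statistic uses that value.
- `doc_cohort_epoch_counts.csv` — per-patient counts of P300 (target) and
  non-P300 (non-target) EEG epochs.
- `p300_accuracy_cnn.csv`, `p300_accuracy_bayesian.csv` — per-patient
  cross-validated P300 detection accuracy (percent, as printed, 2 d.p.) and
  F1 score for the CNN and the variational Bayesian detector.
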