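{
  "sex": {
    "rows": ["female", "male"],
    "cols": ["lung_cancer", "benign"],
    "counts": [[97, 26], [126, 50]]
  },
  "smoking_status": {
    "rows": ["current", "former"],
    "cols": ["lung_cancer", "benign"],
    "counts": [[101, 26], [122, 50]]
  },
  "mass_location": {
    "rows": ["central", "peripheral", "central_and_peripheral"],
    "cols": ["lung_cancer", "benign"],
    "counts": [[86, 16], [60, 30], [60, 18]]
  },
  "test_set_detection": {
    "cancers": 78,
    "bronchoscopy_detected": 40,
    "nondiagnostic_cancers": 38,
    "classifier_detected": 34
  }
}
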