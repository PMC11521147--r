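# Manufacturer-characterized solid calibration phantoms (one wavelength each)
phantoms:
  - name: A
    lambda_nm: 560
    mua: 0.0566
    mus_p: 1.17
  - name: B
    lambda_nm: 633
    mua: 0.0066
    mus_p: 0.491
  - name: C
    lambda_nm: 560
    mua: 0.115
    mus_p: 1.98
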