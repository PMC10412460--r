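model_version: '2.2'
treatments:
  chemotherapy:
    anthracycline: 0.8
    taxane: 0.7
  hormone: 0.71
  trastuzumab: 0.69
strata:
  ER-negative:
    breast:
      terms:
      - predictor: age
        type: continuous
        transform: identity
        ref: 57.0
        scale: 10.0
        coef: 0.12
      - predictor: tumour_size
        type: continuous
        transform: sqrt
        ref: 1.449
        scale: 1.0
        coef: 0.7
      - predictor: positive_nodes
        type: continuous
        transform: log1p
        ref: 0.788
        scale: 1.0
        coef: 0.5
      - predictor: grade
        type: categorical
        coefs:
          '1': -0.7
          '2': 0.0
          '3': 0.25
      - predictor: detection_screen
        type: continuous
        transform: identity
        ref: 0.1
        scale: 1.0
        coef: -0.4
      biomarkers:
      - name: HER2
        hr: 1.25
        prevalence: 0.16
    other:
      terms:
      - predictor: age
        type: continuous
        transform: identity
        ref: 57.0
        scale: 10.0
        coef: 0.9
      biomarkers: []
  ER-positive:
    breast:
      terms:
      - predictor: age
        type: continuous
        transform: identity
        ref: 57.0
        scale: 10.0
        coef: 0.3
      - predictor: tumour_size
        type: continuous
        transform: sqrt
        ref: 1.449
        scale: 1.0
        coef: 0.75
      - predictor: positive_nodes
        type: continuous
        transform: log1p
        ref: 0.788
        scale: 1.0
        coef: 0.55
      - predictor: grade
        type: categorical
        coefs:
          '1': -0.85
          '2': 0.0
          '3': 0.45
      - predictor: detection_screen
        type: continuous
        transform: identity
        ref: 0.25
        scale: 1.0
        coef: -0.55
      biomarkers:
      - name: HER2
        hr: 1.3
        prevalence: 0.16
      - name: KI67
        hr: 1.3
        prevalence: 0.55
    other:
      terms:
      - predictor: age
        type: continuous
        transform: identity
        ref: 57.0
        scale: 10.0
        coef: 0.9
      biomarkers: []
baseline:
  ER-negative:
    breast:
    - 0.0
    - 0.044
    - 0.1
    - 0.154
    - 0.198
    - 0.232
    - 0.258
    - 0.278
    - 0.294
    - 0.308
    - 0.32
    - 0.33
    - 0.34
    - 0.348
    - 0.356
    - 0.364
    other:
    - 0.0
    - 0.0033
    - 0.006798
    - 0.01050588
    - 0.0144362328
    - 0.018602406768
    - 0.023018551174
    - 0.027699664245
    - 0.032661644099
    - 0.037921342745
    - 0.04349662331
    - 0.049406420708
    - 0.055670805951
    - 0.062311054308
    - 0.069349717566
    - 0.07681070062
  ER-positive:
    breast:
    - 0.0
    - 0.008
    - 0.022
    - 0.04
    - 0.06
    - 0.082
    - 0.104
    - 0.126
    - 0.146
    - 0.166
    - 0.184
    - 0.202
    - 0.218
    - 0.234
    - 0.25
    - 0.264
    other:
    - 0.0
    - 0.0033
    - 0.006798
    - 0.01050588
    - 0.0144362328
    - 0.018602406768
    - 0.023018551174
    - 0.027699664245
    - 0.032661644099
    - 0.037921342745
    - 0.04349662331
    - 0.049406420708
    - 0.055670805951
    - 0.062311054308
    - 0.069349717566
    - 0.07681070062
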