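# Small-pulmonary-nodule follow-up statements; the actions carry future
# temporal components ("CT chest in 12 months") that CQL cannot express.
If [pulmonary nodule on chest CT] And [nodule size <=4mm] And [high risk] Then [CT chest in 12 months]
If [pulmonary nodule on chest CT] And [nodule size >4mm] And [nodule size <=6] And [low risk] Then [CT Chest in 12 months]
If [pulmonary nodule on chest CT] And [nodule size >4mm] And [nodule size <=6] And [high risk] Then [CT chest in 6-12 months]
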