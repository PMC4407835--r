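icd9_code	concept_id
204.00	91857003
204.01	91857003
204.02	91857003
205.00	91861009
205.01	91861009
205.10	92811003
208.90	93143009
200.10	46732000
200.20	46732000
202.80	118600007
201.90	118599009
201.91	118599009
203.00	109989006
194.00	126952004
189.00	372064008
189.01	302849000
170.90	307576001
170.70	76909002
171.90	424413001
171.50	302847003
191.60	428061005
191.90	126906006
192.20	23853001
190.50	371973000
155.00	109841003
186.90	363443007
199.10	363346000
196.90	128462008
197.00	128462008
780.60	386661006
285.90	271737000
287.50	302215000
288.00	165517008
288.80	414478003
786.09	271825005
787.01	422587007
784.00	25064002
782.10	271807003
785.60	30746006
789.20	16294009
789.10	80515008
401.90	38341003
250.00	73211009
493.90	195967001
682.90	128045006
070.54	186747009
042.00	86406008
V22.20	77386006
345.90	52448006
585.90	90708001
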