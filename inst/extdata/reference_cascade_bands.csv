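modality,method,band_index
HSI,MASS-Boss,10
HSI,MASS-Boss,44
HSI,MASS-Boss,45
HSI,MASS-Boss,46
HSI,MASS-Boss,52
HSI,MASS-Boss,53
HSI,MASS-Boss,54
HSI,MASS-Boss,81
HSI,MASS-Boss,88
HSI,MASS-Boss,97
HSI,MASS-Boss,154
HSI,MASS-Boss,155
HSI,MASS-Boss,165
HSI,MASS-Boss,166
HSI,MASS-Boss,192
HSI,MASS-Boss,201
HSI,MASS-Boss,207
HSI,MASS-Boss,213
HSI,MASS-Boss,217
HSI,MASS-Boss,218
HSI,MASS-Boss,227
HSI,CARS-Boss,1
HSI,CARS-Boss,2
HSI,CARS-Boss,11
HSI,CARS-Boss,19
HSI,CARS-Boss,45
HSI,CARS-Boss,52
HSI,CARS-Boss,67
HSI,CARS-Boss,82
HSI,CARS-Boss,139
HSI,CARS-Boss,143
HSI,CARS-Boss,148
HSI,CARS-Boss,153
HSI,CARS-Boss,155
HSI,CARS-Boss,165
HSI,CARS-Boss,166
HSI,CARS-Boss,172
HSI,CARS-Boss,173
HSI,CARS-Boss,179
HSI,CARS-Boss,185
HSI,CARS-Boss,194
HSI,CARS-Boss,201
HSI,CARS-Boss,207
HSI,CARS-Boss,212
HSI,CARS-Boss,217
HSI,CARS-Boss,218
HSI,CARS-Boss,219
HSI,CARS-Boss,227
HSI,IVISSA-Boss,1
HSI,IVISSA-Boss,2
HSI,IVISSA-Boss,45
HSI,IVISSA-Boss,52
HSI,IVISSA-Boss,89
HSI,IVISSA-Boss,97
HSI,IVISSA-Boss,147
HSI,IVISSA-Boss,155
HSI,IVISSA-Boss,165
HSI,IVISSA-Boss,166
HSI,IVISSA-Boss,201
HSI,IVISSA-Boss,207
HSI,IVISSA-Boss,209
HSI,IVISSA-Boss,212
HSI,IVISSA-Boss,213
HSI,IVISSA-Boss,217
HSI,IVISSA-Boss,227
FSI,MASS-Boss,3
FSI,MASS-Boss,5
FSI,MASS-Boss,10
FSI,MASS-Boss,14
FSI,MASS-Boss,16
FSI,MASS-Boss,17
FSI,MASS-Boss,22
FSI,MASS-Boss,23
FSI,MASS-Boss,27
FSI,MASS-Boss,29
FSI,MASS-Boss,30
FSI,MASS-Boss,34
FSI,MASS-Boss,42
FSI,MASS-Boss,51
FSI,MASS-Boss,59
FSI,MASS-Boss,60
FSI,MASS-Boss,66
FSI,MASS-Boss,70
FSI,MASS-Boss,75
FSI,MASS-Boss,78
FSI,MASS-Boss,85
FSI,CARS-Boss,3
FSI,CARS-Boss,5
FSI,CARS-Boss,6
FSI,CARS-Boss,10
FSI,CARS-Boss,16
FSI,CARS-Boss,17
FSI,CARS-Boss,22
FSI,CARS-Boss,23
FSI,CARS-Boss,27
FSI,CARS-Boss,29
FSI,CARS-Boss,46
FSI,CARS-Boss,47
FSI,CARS-Boss,51
FSI,CARS-Boss,53
FSI,CARS-Boss,54
FSI,CARS-Boss,55
FSI,CARS-Boss,73
FSI,CARS-Boss,76
FSI,CARS-Boss,79
FSI,CARS-Boss,84
FSI,CARS-Boss,99
FSI,IVISSA-Boss,3
FSI,IVISSA-Boss,6
FSI,IVISSA-Boss,10
FSI,IVISSA-Boss,16
FSI,IVISSA-Boss,22
FSI,IVISSA-Boss,23
FSI,IVISSA-Boss,27
FSI,IVISSA-Boss,29
FSI,IVISSA-Boss,33
FSI,IVISSA-Boss,34
FSI,IVISSA-Boss,47
FSI,IVISSA-Boss,50
FSI,IVISSA-Boss,51
FSI,IVISSA-Boss,65
FSI,IVISSA-Boss,66
FSI,IVISSA-Boss,70
FSI,IVISSA-Boss,76
FSI,IVISSA-Boss,78
FSI,IVISSA-Boss,84
FSI,IVISSA-Boss,99
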