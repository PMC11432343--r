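set_type,image_type,species,n
test,labelled,lotus,387
test,false_positive,lotus,19
train,labelled,lotus,2889
train,false_positive,lotus,144
validation,labelled,lotus,828
validation,false_positive,lotus,41
test,labelled,trifolium,254
test,false_positive,trifolium,12
train,labelled,trifolium,1354
train,false_positive,trifolium,68
validation,labelled,trifolium,391
validation,false_positive,trifolium,20
test,labelled,persicaria,202
test,false_positive,persicaria,10
train,labelled,persicaria,1247
train,false_positive,persicaria,62
validation,labelled,persicaria,369
validation,false_positive,persicaria,18
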