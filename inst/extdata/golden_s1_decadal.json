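{"lentic_mean":[0.00178663435904291,0.00184568340947758,0.0018926602391763,0.00206127804092186,0.00213562243706493,0.00221476273426624,0.00256986999623749,0.0038135279545098,0.00427494607341523,0.0046766384751261,0.00493558780573318,0.00534432486639139,0.00572813060413889,0.00621082288024064,0.00651560610883859,0.00689260373971599,0.00711491632603266],"river_mean":[0.00195100906669541,0.00201381113311066,0.00210735398485374,0.00230544585673622,0.00236636954964925,0.00245001761866938,0.00260023205208246,0.00286527215496159,0.00310330392007602,0.00345522724019855,0.00373288071109634,0.00399449832462248,0.00436555971512926,0.00493023262653731,0.0053686507255808,0.00574930277556018,0.00604667845555682],"decade":[1850,1860,1870,1880,1890,1900,1910,1920,1930,1940,1950,1960,1970,1980,1990,2000,2010]}
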