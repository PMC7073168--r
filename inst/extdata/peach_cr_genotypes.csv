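cultivar,cr_class,cr_hours,SNP_IGA_122351,SNP_IGA_769251,SNP_IGA_779222,SNP_IGA_134905,SNP_IGA_381567,SNP_IGA_786935,SNP_IGA_780662,SNP_IGA_131284,1_40995799,4_13747914,SNP_IGA_427604
Okinawa,low,100,G,G*,C,A,G,A*,C*,G,C,G,G
Flordared,low,100,G,A/G,C,G,A/G,A*,C,A*,G,A/G,G*
Ruby,low,100,A/G,G,C*,A/G*,A/G*,A/G*,C,A/G,C/G*,G,G
Xiami,low,125,G,A/G,C,A,A/G,A*,C,A*,C,A/G*,G
Yinggetao,low,125,G*,G,C,G*,G,A*,C,G,G*,G,G
Premier,low,150,G,A/G,C,A,A/G,A*,C,A,C,A/G*,G
Flordabelle,low,150,A/G*,A/G,T/C,G,G*,A,C,A,C/G*,G*,G
Flordabeauty,low,150,A/G*,G*,C*,A,A,A/G*,C,A,C/G*,A/G,G
TropicPrince,low,150,A/G,G*,C,G,A,G*,C*,A,G,A*,G
Kuu Taur,low,150,A,A*,T,A*,G,A*,C,A,C*,G*,G
Chuenfeng,low,150,G,A/G,C,G,A*,A,C*,A,G,A/G*,G
TropicSweet,low,175,A/G,G,T/C*,G,A/G,A/G,C/A,A*,C/G,A/G,G
SpringHoney,low,180,G,G,C,A/G,A/G,A/G*,C,A/G*,G,A/G,G
Tropicsnow,low,200,A/G,A/G,T/C*,A,G*,A/G*,C/A,A,C,A/G,G
Fushou,low,n.a.,G,A/G,T/C*,A/G,G,A,C/A*,A/G*,G,A/G*,G*
Yamane Hakuto,high,800,A,A,T,A*,A,G,A,G,C,G,A
Shiga Hakuto,high,800,A*,A,T*,A*,A,G,A*,G*,G,A*,A/G*
Okubo,high,850,A,A,T,A,A,G,A,G,C,G,A
Shanghaishuimi,high,850,A,A/G*,T,A,A,A/G*,C/A*,A/G*,C,A/G,A/G*
Okitsu,high,900,A,A,T/C,A,A,A,C/A*,G*,C,A,G
Aki Hakuto,high,900,A,A*,T,A*,A,G*,A,A/G,C,G,A
Hongqingshui,high,N/A,A,A,T,A/G*,A,G,A*,A/G,C*,A*,A
Nakatsu Hakuto,high,N/A,A,A*,T*,A*,A,G,A,G,C,G,A*
Sunago wase,high,N/A,A,A/G*,T,A,A/G,A/G,A,G,C,A/G,A/G*
Yamato Wase,high,N/A,A*,A,T,A/G*,A,G,A*,G,C*,A,A*
Odama Hakuho,high,N/A,A,A,T*,A,A,G*,A,G*,C,G,A*
Tsao Sheng Yu Tao,high,N/A,A,A/G*,C*,A,A*,A/G,C,G,C,A*,G*
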