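tooth,surface,timepoint,median
All,all,T1,7.0
All,all,T2,10.3
All,all,T3,5.9
21,vestibular,T1,2.6
21,vestibular,T2,3.4
21,vestibular,T3,2.2
41,vestibular,T1,3.4
41,vestibular,T2,6.9
41,vestibular,T3,4.2
24,vestibular,T1,7.8
24,vestibular,T2,15.6
24,vestibular,T3,4.8
44,vestibular,T1,6.0
44,vestibular,T2,10.1
44,vestibular,T3,5.5
16,vestibular,T1,12.2
16,vestibular,T2,38.6
16,vestibular,T3,6.2
36,vestibular,T1,10.8
36,vestibular,T2,17.2
36,vestibular,T3,7.7
21,oral,T1,3.6
21,oral,T2,5.3
21,oral,T3,3.8
41,oral,T1,3.9
41,oral,T2,8.2
41,oral,T3,5.9
24,oral,T1,6.2
24,oral,T2,7.0
24,oral,T3,7.4
44,oral,T1,14.7
44,oral,T2,26.9
44,oral,T3,12.7
16,oral,T1,14.4
16,oral,T2,15.0
16,oral,T3,17.2
36,oral,T1,9.5
36,oral,T2,12.8
36,oral,T3,10.2
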