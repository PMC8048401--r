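x,y,t,id,hdop
1780865,2403219,2011-01-01T00:00:30Z,F2,10.5
1781973,2402677,2011-01-01T01:02:29Z,F2,15.1
1781900,2402526,2011-01-01T03:00:20Z,F2,30.5
1781967,2402741,2011-01-01T04:05:30Z,F2,6.4
1781866,2402139,2011-01-01T05:05:01Z,F2,20.5
1781289,2402110,2011-01-01T06:07:05Z,F2,45.8
1781828,2401963,2011-01-01T07:06:06Z,F2,19.7
1782609,2401669,2011-01-01T08:04:24Z,F2,20.2
1782372,2401732,2011-01-01T09:04:07Z,F2,21.2
1782237,2401888,2011-01-01T10:03:08Z,F2,20.5
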