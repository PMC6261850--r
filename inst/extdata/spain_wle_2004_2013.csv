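sex,period,employed,unemployed,inactive,retired,total
male,2004/2005,37.8,2.4,5.8,16.5,62.5
male,2005/2006,36.5,2.2,7.7,16.1,62.2
male,2006/2007,37.5,2.6,6.5,16.6,63.1
male,2007/2008,32.1,4.0,10.8,16.4,63.0
male,2008/2009,25.6,6.7,14.6,16.7,63.6
male,2009/2010,28.5,6.4,12.2,17.0,64.0
male,2010/2011,29.3,5.6,12.3,17.3,64.4
male,2011/2012,26.1,6.2,15.1,17.2,64.5
male,2012/2013,28.8,5.9,12.6,17.4,64.6
female,2004/2005,32.8,3.0,12.3,20.9,68.5
female,2005/2006,30.5,2.7,15.3,20.5,69.0
female,2006/2007,32.6,3.6,12.3,21.0,69.3
female,2007/2008,30.0,4.1,14.6,20.8,69.5
female,2008/2009,25.6,5.4,18.1,20.5,69.6
female,2009/2010,26.6,5.9,16.6,20.9,69.6
female,2010/2011,27.2,5.3,16.8,21.1,69.7
female,2011/2012,24.9,5.4,18.7,21.3,70.3
female,2012/2013,24.7,4.8,19.6,21.3,70.3
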