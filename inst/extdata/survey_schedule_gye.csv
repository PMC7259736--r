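stage,year,n_surveys,first_date,last_date
breeding,2009,0,,
breeding,2010,0,,
breeding,2011,123,2011-03-15,2011-06-10
breeding,2012,0,,
breeding,2013,261,2013-05-19,2013-06-15
early_summer,2009,0,,
early_summer,2010,0,,
early_summer,2011,51,2011-06-16,2011-06-30
early_summer,2012,6,2012-06-22,2012-06-22
early_summer,2013,132,2013-06-16,2013-06-29
late_summer,2009,144,2009-07-15,2009-08-11
late_summer,2010,3,2010-07-15,2010-07-28
late_summer,2011,189,2011-07-07,2011-08-03
late_summer,2012,6,2012-07-12,2012-07-27
late_summer,2013,411,2013-07-12,2013-08-09
fall_harvest,2009,144,2009-08-18,2009-08-30
fall_harvest,2010,0,,
fall_harvest,2011,165,2011-08-16,2011-09-15
fall_harvest,2012,72,2012-08-13,2012-09-06
fall_harvest,2013,612,2013-08-12,2013-09-28
post_harvest,2009,144,2009-09-09,2009-09-22
post_harvest,2010,0,,
post_harvest,2011,0,,
post_harvest,2012,45,2012-09-10,2012-09-27
post_harvest,2013,18,2013-09-29,2013-10-01
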