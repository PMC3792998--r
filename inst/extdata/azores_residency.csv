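species,whale_id,tagging_date,residence_days,ars_percent,track_days,censored,short_track
fin,80716,01/09/2009,6,8.2,18,FALSE,FALSE
fin,80713,17/04/2010,3,100,3,TRUE,TRUE
fin,80702,30/04/2010,13,92.9,18,FALSE,FALSE
fin,80707,30/04/2010,17,98.4,19,FALSE,FALSE
fin,80704,12/05/2010,6,22.2,34,FALSE,FALSE
fin,89969,12/05/2010,4,50.0,55,FALSE,FALSE
fin,80703,26/04/2011,2,100,2,TRUE,TRUE
fin,80715,23/05/2011,3,39.1,14,FALSE,FALSE
fin,60787,15/03/2012,11,59.3,11,TRUE,FALSE
fin,61878,16/03/2012,18,13.8,17,TRUE,FALSE
fin,61699,04/04/2012,22,78.5,21,TRUE,FALSE
fin,60784,20/04/2012,12,90.2,11,TRUE,FALSE
blue,80709,27/04/2009,60,73.5,60,FALSE,FALSE
blue,80700,06/05/2009,45,82.5,45,FALSE,FALSE
blue,80718,20/05/2011,0,NA,22,FALSE,FALSE
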