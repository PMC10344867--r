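"subject_id","age","sex","bmi","af","hf_nyha","digoxin","fatty_liver","exam_date"
"S000001",60.9849671435477,"F",24.2833418404024,FALSE,,FALSE,FALSE,2012-01-27
"S000002",72.0848015071697,"F",22.803606866475,FALSE,,FALSE,TRUE,2016-02-01
"S000003",56.4382067337441,"M",16.799387466693,TRUE,,TRUE,FALSE,2017-01-28
"S000004",55.3899799462354,"F",18.9518642772606,FALSE,,FALSE,FALSE,2015-03-30
"S000005",70.8324851852635,"F",21.6441670969064,TRUE,,FALSE,FALSE,2011-04-21
"S000006",60.7054231819182,"M",19.0547101299755,FALSE,,FALSE,FALSE,2017-04-08
"S000007",59.9565302021388,"M",20.9283145113194,TRUE,,FALSE,TRUE,2011-04-30
"S000008",48.9400194575655,"M",27.7454335643347,FALSE,,FALSE,FALSE,2017-06-27
"S000009",25.8673798907842,"F",23.7696864411717,FALSE,,FALSE,FALSE,2015-08-30
"S000010",54.881908006385,"M",17.3861651422916,FALSE,,FALSE,TRUE,2013-07-16
"S000011",52.8824744443751,"M",17.8033914395397,FALSE,,FALSE,FALSE,2019-04-23
"S000012",65.5045983639283,"F",25.828441239926,FALSE,,FALSE,TRUE,2015-09-07
"S000013",67.056783134949,"M",25.0050591716261,FALSE,,FALSE,FALSE,2016-09-24
"S000014",46.4661310279893,"F",20.9732914542697,TRUE,,FALSE,FALSE,2017-12-20
"S000015",62.8314210663614,"F",22.800878846193,FALSE,,FALSE,FALSE,2011-08-24
"S000016",52.2435382727354,"M",24.4167339364731,FALSE,,FALSE,FALSE,2013-05-18
"S000017",80.1302368682942,"F",13.2286464999887,FALSE,,FALSE,TRUE,2020-11-18
"S000018",58.7406934404812,"M",24.3678294148239,FALSE,,FALSE,TRUE,2018-01-13
"S000019",80.6990471434564,"M",30.1034667787608,FALSE,,FALSE,TRUE,2013-01-17
"S000020",59.1518015587455,"M",20.4319614056726,FALSE,,FALSE,FALSE,2018-02-21
"S000021",77.3974745870352,"F",23.2778207318458,FALSE,,FALSE,FALSE,2012-07-26
"S000022",61.8861243701368,"M",19.9736217292576,FALSE,,FALSE,FALSE,2011-10-20
"S000023",57.1990066200892,"M",19.0001618176383,FALSE,,FALSE,FALSE,2011-02-27
"S000024",62.2638274858545,"M",29.0427435678413,FALSE,,FALSE,FALSE,2020-09-28
"S000025",82.9132085743735,"F",17.1197322550384,FALSE,,FALSE,FALSE,2014-08-03
"S000026",48.7139100883276,"F",26.3889060201264,FALSE,,FALSE,TRUE,2019-12-07
"S000027",49.2741262101222,"M",22.1936847462692,FALSE,,FALSE,FALSE,2011-08-11
"S000028",85.4139358322914,"F",19.4555377098752,TRUE,,FALSE,FALSE,2020-07-22
"S000029",69.2324809112853,"F",24.4240495732289,FALSE,,TRUE,FALSE,2012-07-29
"S000030",37.7526862299755,"F",12.85351283868,FALSE,,FALSE,FALSE,2018-01-22
"S000031",80.0801065145065,"F",24.9623507305553,FALSE,,FALSE,FALSE,2014-08-02
"S000032",73.564533070035,"F",27.5206143956673,FALSE,,FALSE,FALSE,2012-07-31
"S000033",43.3533030534689,"M",20.8913063174954,FALSE,,FALSE,FALSE,2012-12-10
"S000034",52.7162914553154,"M",20.5227576948115,FALSE,,FALSE,FALSE,2019-12-16
"S000035",77.129335466309,"M",18.1754176636513,FALSE,,FALSE,TRUE,2020-04-07
"S000036",67.1414693465727,"F",24.9610813060964,FALSE,,FALSE,FALSE,2012-03-23
"S000037",72.1350024434744,"M",23.5543011757048,TRUE,1,FALSE,FALSE,2015-04-27
"S000038",53.6101933745365,"F",22.3587338977293,FALSE,,FALSE,FALSE,2017-06-17
"S000039",61.2216526809936,"F",20.4608407008752,FALSE,,FALSE,FALSE,2012-10-06
"S000040",67.6518037450827,"F",22.278295237296,FALSE,,FALSE,FALSE,2011-01-31
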