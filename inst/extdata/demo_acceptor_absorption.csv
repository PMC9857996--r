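wavelength_nm,value
250,549.8706293006702
251,602.37610580254534
252,659.0540043511113
253,720.14561834920551
254,785.89711604738375
255,856.55868019033414
256,932.38354182413866
257,1013.6269063234682
258,1100.5447705257436
259,1193.3926307734152
260,1292.4240826626567
261,1397.8893143721643
262,1510.0334965934665
263,1629.0950732964932
264,1755.3039588321519
265,1888.8796481867389
266,2030.0292485491905
267,2178.9454417180082
268,2335.8043882455654
269,2500.7635855773524
270,2673.9596937757187
271,2855.506343703797
272,3045.4919437670687
273,3243.9775024483097
274,3450.9944849071358
275,3666.5427228287572
276,3890.5883974787857
277,4123.0621165337016
278,4363.8571056922228
279,4612.8275363151351
280,4869.7870103752457
281,5134.5072238121265
282,5406.7168289673155
283,5686.1005161161975
284,5972.298333207189
285,6264.9052617641
286,6563.4710655040381
287,6867.5004265742136
288,7176.4533824235832
289,7489.7460742096318
290,7806.7518153105311
291,8126.8024859857951
292,8449.1902575248023
293,8773.1696463662665
294,9097.9598956895006
295,9422.7476789000029
296,9746.6901162893919
297,10068.918092977494
298,10388.539863077965
299,10704.644921905794
300,11016.308125002877
301,11322.594029835111
302,11622.56143324874
303,11915.268075202146
304,12199.775476947685
305,12475.153879760075
306,12740.487248524687
307,12994.878303039042
308,13237.453538768932
309,13467.368198057466
310,13683.811152428178
311,13886.009656663655
312,14073.233935786619
313,14244.801566922877
314,14400.081619282166
315,14538.498517145163
316,14659.535592779674
317,14762.738298607359
318,14847.717050681007
319,14914.149678583331
320,14961.783460189206
321,14990.436723307781
322,15000
323,14990.436723307781
324,14961.783460189206
325,14914.149678583331
326,14847.717050681007
327,14762.738298607359
328,14659.535592779674
329,14538.498517145163
330,14400.081619282166
331,14244.801566922877
332,14073.233935786619
333,13886.009656663655
334,13683.811152428178
335,13467.368198057466
336,13237.453538768932
337,12994.878303039042
338,12740.487248524687
339,12475.153879760075
340,12199.775476947685
341,11915.268075202146
342,11622.56143324874
343,11322.594029835111
344,11016.308125002877
345,10704.644921905794
346,10388.539863077965
347,10068.918092977494
348,9746.6901162893919
349,9422.7476789000029
350,9097.9598956895006
351,8773.1696463662665
352,8449.1902575248023
353,8126.8024859857951
354,7806.7518153105311
355,7489.7460742096318
356,7176.4533824235832
357,6867.5004265742136
358,6563.4710655040381
359,6264.9052617641
360,5972.298333207189
361,5686.1005161161975
362,5406.7168289673155
363,5134.5072238121265
364,4869.7870103752457
365,4612.8275363151351
366,4363.8571056922228
367,4123.0621165337016
368,3890.5883974787857
369,3666.5427228287572
370,3450.9944849071358
371,3243.9775024483097
372,3045.4919437670687
373,2855.506343703797
374,2673.9596937757187
375,2500.7635855773524
376,2335.8043882455654
377,2178.9454417180082
378,2030.0292485491905
379,1888.8796481867389
380,1755.3039588321519
381,1629.0950732964932
382,1510.0334965934665
383,1397.8893143721643
384,1292.4240826626567
385,1193.3926307734152
386,1100.5447705257436
387,1013.6269063234682
388,932.38354182413866
389,856.55868019033414
390,785.89711604738375
391,720.14561834920551
392,659.0540043511113
393,602.37610580254534
394,549.8706293006702
395,501.30191348549272
396,456.44058640817855
397,415.06412696676284
398,376.95733477911625
399,341.91271325418518
400,309.73077093241693
401,280.22024639882289
402,253.19826223184864
403,228.49041354307676
404,205.93079669212509
405,185.36198373352818
406,166.6349480736346
407,149.60894669145486
408,134.15136411373734
409,120.13752313704373
410,107.45046706378825
411,95.980717970415981
412,85.626015259190424
413,76.29103846519051
414,67.887118001500781
415,60.331937232268174
416,53.549228968978305
417,47.468469193265875
418,42.024570522727267
419,37.157577657078477
420,32.812366772743275
421,28.938350576369256
422,25.489190483289857
423,22.422517156716058
424,19.69966042826935
425,17.285389420912733
426,15.147663511690222
427,13.25739460402575
428,11.588221027525057
429,10.116293246972841
430,8.8200714410683432
431,7.68013490482255
432,6.6790031367728506
433,5.8009683924994899
434,5.0319394185376778
435,4.3592960248108135
436,3.7717541082822978
437,3.2592407047424152
438,2.8127786186225769
439,2.4243801615859804
440,2.0869495185285061
441,1.7941932537153655
442,1.5405384692948283
443,1.3210581326298638
444,1.1314030970781417
445,0.96774035238693479
446,0.82669705515786984
447,0.70530990633574808
448,0.60097946089426602
449,0.51142897438878643
450,0.43466741143006649
451,0.36895626205734272
452,0.31277983315337682
453,0.26481870318822182
454,0.22392604948206682
455,0.18910657765572783
456,0.15949780283830495
457,0.13435345140327898
458,0.11302877041174386
459,0.094967549483434194
460,0.079690676442791236
461,0.066786063767084763
462,0.055899797581180063
463,0.046728374697213422
464,0.039011905997020237
465,0.032528176320058041
466,0.027087461976913932
467,0.022528017091610113
468,0.018712149222855169
469,0.01552281316664063
470,0.012860659544005179
471,0.010641481773654531
472,0.0087940113652805896
473,0.0072580171916309137
474,0.0059826695507305041
475,0.0049251344581225367
476,0.0040493677550445207
477,0.0033250823227923697
478,0.0027268649948561279
479,0.0022334226933193742
480,0.0018269399188572651
481,0.0014925320265399321
482,0.0012177807523716081
483,0.00099234024565465501
484,0.00080760343525565655
485,0.0006564199369497683
486,0.00053285791548791895
487,0.00043200336820623056
488,0.00034979121440319047
489,0.00028286337217517491
490,0.00022844969617068944
491,0.00018426824857985179
492,0.00014844189304907799
493,0.00011942864729484564
494,9.5963614046557446e-05
495,7.7010639610587255e-05
496,6.1722131917578914e-05
497,4.9405711654591213e-05
498,3.9496576498713753e-05
499,3.1534634388365346e-05
500,2.5145611417247825e-05
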