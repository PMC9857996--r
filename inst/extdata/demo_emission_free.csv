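wavelength_nm,value
250,0.21874911181828852
251,0.25620638631224368
252,0.29945826284881294
253,0.34928935341757211
254,0.40657165060809303
255,0.47227127900757021
256,0.54745531223510846
257,0.63329857531311717
258,0.73109033924913103
259,0.84224080146009273
260,0.96828723221387436
261,1.1108996538242306
262,1.2718859061862213
263,1.4531959396856664
264,1.6569251648978929
265,1.8853166781773658
266,2.1407621736259546
267,2.4258013454282268
268,2.7431195805845734
269,3.0955437410882074
270,3.4860358370052462
271,3.9176843981361773
272,4.3936933623407421
273,4.9173683135333466
274,5.4920999220831286
275,6.1213444650931592
276,6.8086013339146918
277,7.5573874713060807
278,8.3712087207943267
279,9.2535281158421991
280,10.207731186039187
281,11.23708841125673
282,12.344715011935547
283,13.533528323661271
284,14.806203066053209
285,16.165124878726996
286,17.612342559561654
287,19.149519501466301
288,20.777884881975261
289,22.498185213913452
290,24.310636913641176
291,26.21488058457631
292,28.209937746398424
293,30.294170763221238
294,32.465246735834974
295,34.720106122762971
296,37.05493684141625
297,39.465154573342701
298,41.945389955974221
299,44.489483287164319
300,47.090487298266154
301,49.740678466922553
302,52.431577242846942
303,55.153977449716429
304,57.897985005247378
305,60.653065971263345
306,63.408103808068482
307,66.151465564937467
308,68.871076593480794
309,71.554503225670089
310,74.189042716164963
311,76.761819612088544
312,79.259887585374173
313,81.670335646008397
314,83.980397551556891
315,86.177563141715638
316,88.249690258459552
317,90.185115864528271
318,91.972764946990182
319,93.602255789541474
320,95.064000217660663
321,96.349297464906797
322,97.450420376188191
323,98.360692753912787
324,99.074556764253373
325,99.587629451549844
326,99.896747556932169
327,100
328,99.896747556932169
329,99.587629451549844
330,99.074556764253373
331,98.360692753912787
332,97.450420376188191
333,96.349297464906797
334,95.064000217660663
335,93.602255789541474
336,91.972764946990182
337,90.185115864528271
338,88.249690258459552
339,86.177563141715638
340,83.980397551556891
341,81.670335646008397
342,79.259887585374173
343,76.761819612088544
344,74.189042716164963
345,71.554503225670089
346,68.871076593480794
347,66.151465564937467
348,63.408103808068482
349,60.653065971263345
350,57.897985005247378
351,55.153977449716429
352,52.431577242846942
353,49.740678466922553
354,47.090487298266154
355,44.489483287164319
356,41.945389955974221
357,39.465154573342701
358,37.05493684141625
359,34.720106122762971
360,32.465246735834974
361,30.294170763221238
362,28.209937746398424
363,26.21488058457631
364,24.310636913641176
365,22.498185213913452
366,20.777884881975261
367,19.149519501466301
368,17.612342559561654
369,16.165124878726996
370,14.806203066053209
371,13.533528323661271
372,12.344715011935547
373,11.23708841125673
374,10.207731186039187
375,9.2535281158421991
376,8.3712087207943267
377,7.5573874713060807
378,6.8086013339146918
379,6.1213444650931592
380,5.4920999220831286
381,4.9173683135333466
382,4.3936933623407421
383,3.9176843981361773
384,3.4860358370052462
385,3.0955437410882074
386,2.7431195805845734
387,2.4258013454282268
388,2.1407621736259546
389,1.8853166781773658
390,1.6569251648978929
391,1.4531959396856664
392,1.2718859061862213
393,1.1108996538242306
394,0.96828723221387436
395,0.84224080146009273
396,0.73109033924913103
397,0.63329857531311717
398,0.54745531223510846
399,0.47227127900757021
400,0.40657165060809303
401,0.34928935341757211
402,0.29945826284881294
403,0.25620638631224368
404,0.21874911181828852
405,0.18638259026584011
406,0.15847730792202058
407,0.13447189485709041
408,0.1138672052277198
409,0.096220696343136486
410,0.08114112541975442
411,0.068283575828252951
412,0.057344818442985612
413,0.048059008383122596
414,0.040193712942831944
415,0.033546262790251184
416,0.027940415512017064
417,0.023223318227836916
418,0.019262754232164933
419,0.015944657371392737
420,0.013170877070117531
421,0.010857176516351791
422,0.0089314464435409253
423,0.0073321171513971196
424,0.0060067518366626925
425,0.0049108049124716177
426,0.0040065297392951069
427,0.003262021034666128
428,0.0026503781408387813
429,0.0021489762816443974
430,0.0017388339087321557
431,0.0014040652037771474
432,0.001131407751390459
433,0.00090981631494148167
434,0.00073011452478844829
435,0.00058469711855359979
436,0.00046727615133038901
437,0.00037266531720786707
438,0.00029659719095164876
439,0.00023556881009121762
440,0.00018671157406450261
441,0.00014768194030451815
442,0.00011656984966862685
443,9.1822218292429979e-05
444,7.2179192968440883e-05
445,5.6621185839471936e-05
446,4.4324984955527286e-05
447,3.4627483449236602e-05
448,2.6995785033630141e-05
449,2.1002630380653774e-05
450,1.6306250695371969e-05
451,1.263389426415538e-05
452,9.7683915241740709e-06
453,7.5372266621774491e-06
454,5.8036710750835473e-06
455,4.4596081759274868e-06
456,3.4197417669125702e-06
457,2.6169330958211961e-06
458,1.9984561527098375e-06
459,1.522997974471263e-06
460,1.1582617772144826e-06
461,8.7905656405453777e-07
462,6.657782679439929e-07
463,5.0320518349963336e-07
464,3.7954501751071514e-07
465,2.8568285699713395e-07
466,2.1458915201591018e-07
467,1.6085480706634977e-07
468,1.2032698143810564e-07
469,8.9824476998893663e-08
470,6.6915860912927819e-08
471,4.9746913407952975e-08
472,3.6906758838199826e-08
473,2.7324257640306506e-08
474,2.0188011043211871e-08
475,1.4884744797568415e-08
476,1.0951962539585384e-08
477,8.0416506757077895e-09
478,5.8925212188756079e-09
479,4.308834405121081e-09
480,3.1442795413735374e-09
481,2.2897348456455529e-09
482,1.6639946827005351e-09
483,1.2067612947591367e-09
484,8.7336042335089561e-10
485,6.307660944528387e-10
486,4.5461720843956545e-10
487,3.269836959522875e-10
488,2.3469780253206939e-10
489,1.6811042480404839e-10
490,1.2016637637715247e-10
491,8.5718385424926371e-11
492,6.1019366776053234e-11
493,4.3347505276241423e-11
494,3.073004648073067e-11
495,2.1740274509129157e-11
496,1.5348626829351854e-11
497,1.0813760041412248e-11
498,7.6030286448975317e-12
499,5.3345675949066703e-12
500,3.7352056307808265e-12
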