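wavelength_nm,value
250,0.00090981631494148167
251,0.001131407751390459
252,0.0014040652037771474
253,0.0017388339087321557
254,0.0021489762816443974
255,0.0026503781408387813
256,0.003262021034666128
257,0.0040065297392951069
258,0.0049108049124716177
259,0.0060067518366626925
260,0.0073321171513971196
261,0.0089314464435409253
262,0.010857176516351791
263,0.013170877070117531
264,0.015944657371392737
265,0.019262754232164933
266,0.023223318227836916
267,0.027940415512017064
268,0.033546262790251184
269,0.040193712942831944
270,0.048059008383122596
271,0.057344818442985612
272,0.068283575828252951
273,0.08114112541975442
274,0.096220696343136486
275,0.1138672052277198
276,0.13447189485709041
277,0.15847730792202058
278,0.18638259026584011
279,0.21874911181828852
280,0.25620638631224368
281,0.29945826284881294
282,0.34928935341757211
283,0.40657165060809303
284,0.47227127900757021
285,0.54745531223510846
286,0.63329857531311717
287,0.73109033924913103
288,0.84224080146009273
289,0.96828723221387436
290,1.1108996538242306
291,1.2718859061862213
292,1.4531959396856664
293,1.6569251648978929
294,1.8853166781773658
295,2.1407621736259546
296,2.4258013454282268
297,2.7431195805845734
298,3.0955437410882074
299,3.4860358370052462
300,3.9176843981361773
301,4.3936933623407421
302,4.9173683135333466
303,5.4920999220831286
304,6.1213444650931592
305,6.8086013339146918
306,7.5573874713060807
307,8.3712087207943267
308,9.2535281158421991
309,10.207731186039187
310,11.23708841125673
311,12.344715011935547
312,13.533528323661271
313,14.806203066053209
314,16.165124878726996
315,17.612342559561654
316,19.149519501466301
317,20.777884881975261
318,22.498185213913452
319,24.310636913641176
320,26.21488058457631
321,28.209937746398424
322,30.294170763221238
323,32.465246735834974
324,34.720106122762971
325,37.05493684141625
326,39.465154573342701
327,41.945389955974221
328,44.489483287164319
329,47.090487298266154
330,49.740678466922553
331,52.431577242846942
332,55.153977449716429
333,57.897985005247378
334,60.653065971263345
335,63.408103808068482
336,66.151465564937467
337,68.871076593480794
338,71.554503225670089
339,74.189042716164963
340,76.761819612088544
341,79.259887585374173
342,81.670335646008397
343,83.980397551556891
344,86.177563141715638
345,88.249690258459552
346,90.185115864528271
347,91.972764946990182
348,93.602255789541474
349,95.064000217660663
350,96.349297464906797
351,97.450420376188191
352,98.360692753912787
353,99.074556764253373
354,99.587629451549844
355,99.896747556932169
356,100
357,99.896747556932169
358,99.587629451549844
359,99.074556764253373
360,98.360692753912787
361,97.450420376188191
362,96.349297464906797
363,95.064000217660663
364,93.602255789541474
365,91.972764946990182
366,90.185115864528271
367,88.249690258459552
368,86.177563141715638
369,83.980397551556891
370,81.670335646008397
371,79.259887585374173
372,76.761819612088544
373,74.189042716164963
374,71.554503225670089
375,68.871076593480794
376,66.151465564937467
377,63.408103808068482
378,60.653065971263345
379,57.897985005247378
380,55.153977449716429
381,52.431577242846942
382,49.740678466922553
383,47.090487298266154
384,44.489483287164319
385,41.945389955974221
386,39.465154573342701
387,37.05493684141625
388,34.720106122762971
389,32.465246735834974
390,30.294170763221238
391,28.209937746398424
392,26.21488058457631
393,24.310636913641176
394,22.498185213913452
395,20.777884881975261
396,19.149519501466301
397,17.612342559561654
398,16.165124878726996
399,14.806203066053209
400,13.533528323661271
401,12.344715011935547
402,11.23708841125673
403,10.207731186039187
404,9.2535281158421991
405,8.3712087207943267
406,7.5573874713060807
407,6.8086013339146918
408,6.1213444650931592
409,5.4920999220831286
410,4.9173683135333466
411,4.3936933623407421
412,3.9176843981361773
413,3.4860358370052462
414,3.0955437410882074
415,2.7431195805845734
416,2.4258013454282268
417,2.1407621736259546
418,1.8853166781773658
419,1.6569251648978929
420,1.4531959396856664
421,1.2718859061862213
422,1.1108996538242306
423,0.96828723221387436
424,0.84224080146009273
425,0.73109033924913103
426,0.63329857531311717
427,0.54745531223510846
428,0.47227127900757021
429,0.40657165060809303
430,0.34928935341757211
431,0.29945826284881294
432,0.25620638631224368
433,0.21874911181828852
434,0.18638259026584011
435,0.15847730792202058
436,0.13447189485709041
437,0.1138672052277198
438,0.096220696343136486
439,0.08114112541975442
440,0.068283575828252951
441,0.057344818442985612
442,0.048059008383122596
443,0.040193712942831944
444,0.033546262790251184
445,0.027940415512017064
446,0.023223318227836916
447,0.019262754232164933
448,0.015944657371392737
449,0.013170877070117531
450,0.010857176516351791
451,0.0089314464435409253
452,0.0073321171513971196
453,0.0060067518366626925
454,0.0049108049124716177
455,0.0040065297392951069
456,0.003262021034666128
457,0.0026503781408387813
458,0.0021489762816443974
459,0.0017388339087321557
460,0.0014040652037771474
461,0.001131407751390459
462,0.00090981631494148167
463,0.00073011452478844829
464,0.00058469711855359979
465,0.00046727615133038901
466,0.00037266531720786707
467,0.00029659719095164876
468,0.00023556881009121762
469,0.00018671157406450261
470,0.00014768194030451815
471,0.00011656984966862685
472,9.1822218292429979e-05
473,7.2179192968440883e-05
474,5.6621185839471936e-05
475,4.4324984955527286e-05
476,3.4627483449236602e-05
477,2.6995785033630141e-05
478,2.1002630380653774e-05
479,1.6306250695371969e-05
480,1.263389426415538e-05
481,9.7683915241740709e-06
482,7.5372266621774491e-06
483,5.8036710750835473e-06
484,4.4596081759274868e-06
485,3.4197417669125702e-06
486,2.6169330958211961e-06
487,1.9984561527098375e-06
488,1.522997974471263e-06
489,1.1582617772144826e-06
490,8.7905656405453777e-07
491,6.657782679439929e-07
492,5.0320518349963336e-07
493,3.7954501751071514e-07
494,2.8568285699713395e-07
495,2.1458915201591018e-07
496,1.6085480706634977e-07
497,1.2032698143810564e-07
498,8.9824476998893663e-08
499,6.6915860912927819e-08
500,4.9746913407952975e-08
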