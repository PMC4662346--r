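code,name,country,longitude,latitude,altitude,genotyped,mean_budburst,mean_dbh,mean_form
185,Blakeney,UK,-2.5,51.78,76,no,1.08,120,4.24
217,Berce,France,0.39,47.81,155,yes,1.59,98,4.2
237,Reno Valdieu,France,0.67,48.5,230,yes,1.65,116,4.14
210,Saint Germain,France,2.08,48.9,60,yes,1.71,113,4.13
194,Soudrain,France,2.38,46.95,178,yes,1.24,110,4.33
211,Premery,France,3.6,47.2,300,yes,1.55,106,4.34
201,La Haie Renaut,France,4.95,48.67,180,yes,1.77,109,4.24
245,Etangs,France,4.96,46.93,200,yes,2.4,113,4.19
233,Vacheres,France,5.63,43.98,650,yes,3.69,94,4.15
230,Romersberg,France,6.73,48.82,220,no,1.06,101,4.17
250,Cochem,Germany,7.05,50.08,400,yes,1.86,112,4.43
225,Still,France,7.25,48.58,688,yes,1.55,105,4.56
252,Johanneskreuz,Germany,7.83,49.4,460,yes,1.03,116,4.42
257,Wolfgang,Germany,9.05,50.15,160,yes,1.61,96,3.92
181,Horbylunde,Denmark,9.41,56.13,80,yes,0.88,89,3.99
255,Spakensehl,Germany,10.6,52.8,115,yes,0.54,102,4.74
248,Kloster-marienberg,Austria,16.57,47.41,310,yes,3.23,103,3.9
179,Sycow,Poland,17.93,51.18,210,yes,1.42,104,4.76
249,Bolu,Turkey,31.67,40.92,1200,yes,1.58,94,4.39
184,Telavi,Georgia,45.47,41.88,700,no,3.79,77,3.06
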