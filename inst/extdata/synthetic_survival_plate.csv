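"batch","material","conc_ug_mL","dose_Gy","dmso_M","replicate","luminescence"
1,"none",0,0,0,1,220017.812294316
1,"none",0,0,0,2,199733.92076618
1,"none",0,0,0,3,209212.076665213
1,"none",0,0,0,4,212050.986953431
1,"none",0,0,0,5,209642.598743266
1,"none",0,0,0,6,204363.537883427
1,"none",0,2,0,1,203472.792649641
1,"none",0,2,0,2,187780.433315932
1,"none",0,2,0,3,208692.435047204
1,"none",0,2,0,4,188080.417200741
1,"none",0,2,0,5,201382.509290615
1,"none",0,2,0,6,211508.307948325
1,"none",0,4,0,1,159972.780420805
1,"none",0,4,0,2,169097.019867125
1,"none",0,4,0,3,170330.635705452
1,"none",0,4,0,4,177005.542128684
1,"none",0,4,0,5,169050.856391747
1,"none",0,4,0,6,150154.310381256
1,"none",0,6,0,1,136517.960576745
1,"none",0,6,0,2,164739.895592186
1,"none",0,6,0,3,151878.522922375
1,"none",0,6,0,4,141089.372790739
1,"none",0,6,0,5,152904.396650151
1,"none",0,6,0,6,163874.222551171
1,"none",0,8,0,1,150913.058362104
1,"none",0,8,0,2,134356.047573205
1,"none",0,8,0,3,135523.889341858
1,"none",0,8,0,4,125700.267078539
1,"none",0,8,0,5,140469.991082792
1,"none",0,8,0,6,132956.711690151
1,"TiO2",160,0,0,1,210179.444363483
1,"TiO2",160,0,0,2,212814.999359719
1,"TiO2",160,0,0,3,216356.225863065
1,"TiO2",160,2,0,1,154917.595838819
1,"TiO2",160,2,0,2,163784.68174332
1,"TiO2",160,2,0,3,146573.029829018
1,"TiO2",160,4,0,1,110771.898881495
1,"TiO2",160,4,0,2,110404.706730676
1,"TiO2",160,4,0,3,102108.558941018
1,"TiO2",160,6,0,1,77251.1029004223
1,"TiO2",160,6,0,2,77909.6397900707
1,"TiO2",160,6,0,3,75733.0451189929
1,"TiO2",160,8,0,1,49747.4371685368
1,"TiO2",160,8,0,2,46189.9334814779
1,"TiO2",160,8,0,3,44732.6247517918
1,"HfO2",320,0,0,1,209941.887082172
1,"HfO2",320,0,0,2,197286.903689283
1,"HfO2",320,0,0,3,220823.417468531
1,"HfO2",320,2,0,1,154638.462370993
1,"HfO2",320,2,0,2,163270.881328615
1,"HfO2",320,2,0,3,160570.79793336
1,"HfO2",320,4,0,1,107831.390035206
1,"HfO2",320,4,0,2,121325.072160831
1,"HfO2",320,4,0,3,115799.609256057
1,"HfO2",320,6,0,1,73769.934470217
1,"HfO2",320,6,0,2,74461.7024645561
1,"HfO2",320,6,0,3,75975.3744374416
1,"HfO2",320,8,0,1,44581.8483089537
1,"HfO2",320,8,0,2,38216.8627023313
1,"HfO2",320,8,0,3,45018.4859303697
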