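mode,reconstruction,metric,insert,value
head,FBP,noise_magnitude_hu,,40.0
head,IR,noise_magnitude_hu,,26.0
thorax,FBP,noise_magnitude_hu,,10.6
thorax,IR,noise_magnitude_hu,,8.6
pelvis_large,FBP,noise_magnitude_hu,,4.8
pelvis_large,IR,noise_magnitude_hu,,3.6
head,FBP,fpeak_high_mm,,0.29
head,IR,fpeak_high_mm,,0.20
thorax,FBP,fpeak_low_mm,,0.02
thorax,FBP,fpeak_high_mm,,0.22
thorax,IR,fpeak_low_mm,,0.02
thorax,IR,fpeak_high_mm,,0.13
pelvis_large,FBP,fpeak_low_mm,,0.02
pelvis_large,FBP,fpeak_high_mm,,0.22
pelvis_large,IR,fpeak_low_mm,,0.02
pelvis_large,IR,fpeak_high_mm,,0.13
head,FBP,f50_mm,air,0.41
head,FBP,f50_mm,ldpe,0.39
head,FBP,f50_mm,delrin,0.40
head,FBP,f50_mm,teflon,0.39
head,IR,f50_mm,air,0.44
head,IR,f50_mm,ldpe,0.41
head,IR,f50_mm,delrin,0.42
head,IR,f50_mm,teflon,0.40
thorax,FBP,f50_mm,air,0.29
thorax,FBP,f50_mm,ldpe,0.28
thorax,FBP,f50_mm,delrin,0.32
thorax,FBP,f50_mm,teflon,0.28
thorax,IR,f50_mm,air,0.32
thorax,IR,f50_mm,ldpe,0.31
thorax,IR,f50_mm,delrin,0.36
thorax,IR,f50_mm,teflon,0.31
pelvis_large,FBP,f50_mm,air,0.29
pelvis_large,FBP,f50_mm,ldpe,0.29
pelvis_large,FBP,f50_mm,delrin,0.33
pelvis_large,FBP,f50_mm,teflon,0.28
pelvis_large,IR,f50_mm,air,0.32
pelvis_large,IR,f50_mm,ldpe,0.32
pelvis_large,IR,f50_mm,delrin,0.36
pelvis_large,IR,f50_mm,teflon,0.31
head,FBP,dprime,air,14.7
head,FBP,dprime,ldpe,2.5
head,FBP,dprime,delrin,3.4
head,FBP,dprime,teflon,11.8
head,IR,dprime,air,22.5
head,IR,dprime,ldpe,4.0
head,IR,dprime,delrin,5.3
head,IR,dprime,teflon,18.1
thorax,FBP,dprime,air,44.9
thorax,FBP,dprime,ldpe,8.0
thorax,FBP,dprime,delrin,10.5
thorax,FBP,dprime,teflon,35.2
thorax,IR,dprime,air,67.2
thorax,IR,dprime,ldpe,11.6
thorax,IR,dprime,delrin,16.7
thorax,IR,dprime,teflon,51.5
pelvis_large,FBP,dprime,air,105.2
pelvis_large,FBP,dprime,ldpe,18.5
pelvis_large,FBP,dprime,delrin,25.1
pelvis_large,FBP,dprime,teflon,81.6
pelvis_large,IR,dprime,air,192.0
pelvis_large,IR,dprime,ldpe,33.4
pelvis_large,IR,dprime,delrin,46.7
pelvis_large,IR,dprime,teflon,143.4
head,FBP,contrast_hu,air,-1005.6
head,FBP,contrast_hu,ldpe,-181.3
head,FBP,contrast_hu,delrin,237.7
head,FBP,contrast_hu,teflon,808.3
head,IR,contrast_hu,air,-1004.5
head,IR,contrast_hu,ldpe,-180.8
head,IR,contrast_hu,delrin,239.4
head,IR,contrast_hu,teflon,812.8
thorax,FBP,contrast_hu,air,-1024.0
thorax,FBP,contrast_hu,ldpe,-178.3
thorax,FBP,contrast_hu,delrin,234.7
thorax,FBP,contrast_hu,teflon,786.8
thorax,IR,contrast_hu,air,-1023.0
thorax,IR,contrast_hu,ldpe,-178.6
thorax,IR,contrast_hu,delrin,236.5
thorax,IR,contrast_hu,teflon,792.0
pelvis_large,FBP,contrast_hu,air,-1025.0
pelvis_large,FBP,contrast_hu,ldpe,-177.9
pelvis_large,FBP,contrast_hu,delrin,233.1
pelvis_large,FBP,contrast_hu,teflon,776.1
pelvis_large,IR,contrast_hu,air,-1024.8
pelvis_large,IR,contrast_hu,ldpe,-178.0
pelvis_large,IR,contrast_hu,delrin,234.4
pelvis_large,IR,contrast_hu,teflon,781.0
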