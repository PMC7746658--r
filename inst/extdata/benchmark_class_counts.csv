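species,class_label,group,n_train,n_test
Apple,1. Botryospaeria obtuse,diseased,10,46
Apple,2. Venturia inaequalis,diseased,13,58
Apple,3. Gymnosporangium juniperi-virginianae,diseased,15,30
Apple,A. Healthy,healthy,20,162
Blueberry,B. Healthy,healthy,22,117
Cherry,4. Podosphaera spp.,diseased,19,98
Cherry,C. Healthy,healthy,14,76
Corn,5. Cercospora zeae-maydis,diseased,27,32
Corn,6. Puccinia sorghi,diseased,25,90
Corn,7. Exserohilum turcicum,diseased,24,69
Corn,D. Healthy,healthy,27,85
Grape,8. Guignardia bidwellii,diseased,28,94
Grape,9. Phaeomoniella spp.,diseased,21,117
Grape,10. Pseudocercospora vitis,diseased,26,90
Grape,E. Healthy,healthy,26,31
Orange,11. Candidatus Liberibacter,diseased,28,467
Peach,12. Xanthomonas campestris,diseased,27,187
Peach,F. Healthy,healthy,24,26
Pepper,13. Xanthomonas campestris,diseased,16,96
Pepper,G. Healthy,healthy,22,105
Potato,14. Alternaria solani,diseased,16,81
Potato,15. Phytophthora Infestans,diseased,24,58
Potato,H. Healthy,healthy,22,15
Squash,16. Erysiphe cichoracearum,diseased,28,168
Strawberry,17. Diplocarpon earlianum,diseased,25,65
Strawberry,I. Healthy,healthy,28,40
Raspberry,J. Healthy,healthy,19,51
Soybean,K. Healthy,healthy,28,378
Tomato,18. Xanthomonas campestris pv. vesicatoria,diseased,27,163
Tomato,19. Alternaria solani,diseased,25,93
Tomato,20. Phytophthora Infestans,diseased,28,142
Tomato,21. Fulvia fulva,diseased,24,70
Tomato,22. Septoria lycopersici,diseased,28,136
Tomato,23. Tetranychus urticae,diseased,27,149
Tomato,24. Corynespora cassiicola,diseased,21,121
Tomato,25. Mosaic Virus,diseased,20,416
Tomato,26. Yellow leaf curl virus,diseased,25,26
Tomato,L. Healthy,healthy,24,136
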