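# optoclamp illumination series v1
# far_edge_mm: -Inf
# direction: longitudinal
# phase: diastole
b_mm	delta_e_mV
-2	1.3069770770884
-1.67142857142857	1.09371782139514
-1.34285714285714	1.56851146074047
-1.01428571428571	2.11874095061152
-0.685714285714286	2.66633239593959
-0.357142857142857	3.42697916068597
-0.0285714285714285	4.53570657620765
0.3	5.08878291885405
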