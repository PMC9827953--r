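taxon_group,coef,estimate,ci_lb,ci_ub
mammal,intercept,0.00,-0.45,0.45
mammal,distance,0.45,0.02,0.88
mammal,distance2,-0.16,-0.32,-0.02
mammal,diet,0.02,0.01,0.03
mammal,bm,-0.08,-0.26,0.10
mammal,habitat_open,0.29,-0.05,0.63
mammal,distance:diet,-0.01,-0.01,0.00
mammal,distance:bm,-0.20,-0.37,-0.03
mammal,distance2:bm,0.09,0.04,0.14
mammal,distance:habitat_open,-0.23,-0.37,-0.08
bird,intercept,0.05,-0.32,0.42
bird,distance,-0.04,-0.13,0.04
bird,diet,-0.01,-0.02,-0.01
bird,habitat_open,-0.47,-0.87,-0.06
bird,infra_paved_road,-0.45,-0.80,-0.10
bird,infra_power_line,-0.29,-0.70,0.13
bird,infra_unpaved_road,-0.32,-0.75,0.12
bird,distance:diet,0.01,0.01,0.01
bird,distance:habitat_open,0.34,0.20,0.54
reptile,intercept,0.18,-0.27,0.63
reptile,distance,-0.44,-0.87,0.00
reptile,distance2,0.15,0.03,0.28
reptile,habitat_open,-0.67,-1.25,-0.08
reptile,distance:habitat_open,0.38,0.09,0.67
amphibian,intercept,-0.74,-1.15,-0.33
amphibian,distance,0.91,0.21,1.62
amphibian,distance2,-0.32,-0.64,0.00
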