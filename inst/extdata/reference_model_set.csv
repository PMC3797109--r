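name,k,loglik,intercept,mass,nao,mass_nao,mass2,mass2_nao
Mass^2 * NAO,6,-169.018,-0.09,0.11,-0.58,NA,-0.14,-0.27
Mass * NAO,5,-170.293,-0.21,-0.01,-0.79,-0.29,NA,NA
NAO,3,-174.799,-0.21,NA,-0.79,NA,NA,NA
Mass + NAO,4,-173.832,-0.22,0.10,-0.81,NA,NA,NA
Mass^2 + NAO,5,-173.625,-0.18,0.12,-0.80,NA,-0.03,NA
Null,2,-182.591,-0.45,NA,NA,NA,NA,NA
Mass,3,-181.778,-0.46,0.09,NA,NA,NA,NA
Mass^2,4,-181.503,-0.41,0.12,NA,NA,-0.04,NA
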