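group,label,sd,ie,iqmfv
chest_models,original,49.2172,5.5966,2422.3
chest_models,rpca,55.0057,6.1122,3025.6
chest_models,ladmap,54.4365,6.0759,2963.3
chest_models,godec,57.1869,6.0368,3270.3
stomach_models,original,68.0978,3.9737,4637.3
stomach_models,rpca,75.8182,4.7177,5748.4
stomach_models,ladmap,75.1148,4.7347,5642.2
stomach_models,godec,76.3726,4.6915,5832.7
chest_methods,original,50.3358,5.5876,2533.7
chest_methods,wang,50.2142,5.2891,2521.5
chest_methods,hussien,50.4130,5.7766,2541.5
chest_methods,sequence_lowrank,54.5948,6.0645,2980.6
lung_methods,original,47.2274,5.5265,2230.4
lung_methods,wang,46.7205,5.2103,2182.8
lung_methods,hussien,48.6962,5.8733,2371.3
lung_methods,sequence_lowrank,54.3555,6.0751,2954.5
stomach1_methods,original,71.1016,4.2681,5055.4
stomach1_methods,wang,71.9176,4.9294,5172.1
stomach1_methods,hussien,67.9674,4.9868,4619.5
stomach1_methods,sequence_lowrank,74.0204,4.6054,5479.0
stomach2_methods,original,71.1016,4.2681,5055.4
stomach2_methods,wang,71.9176,4.9294,5172.1
stomach2_methods,hussien,71.3398,5.1978,5089.3
stomach2_methods,sequence_lowrank,78.4211,4.8226,6149.9
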