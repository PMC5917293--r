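"time_s","peak_velocity_m_s"
0,0.446155836354317
0.0275735294117647,0.510368512674748
0.0551470588235294,0.562545057199578
0.0827205882352941,0.600104373749529
0.110294117647059,0.622270329818567
0.137867647058824,0.63
0.165441176470588,0.625671497541505
0.193014705882353,0.612585315906071
0.220588235294118,0.594360346498197
0.248161764705882,0.574320424433075
0.275735294117647,0.554967197450171
0.303308823529412,0.537620380043158
0.330882352941176,0.522279349711305
0.358455882352941,0.507724753792686
0.386029411764706,0.491840757108244
0.413602941176471,0.472103621201751
0.441176470588235,0.446155836354317
0.46875,0.412371101624415
0.496323529411765,0.370316220647995
0.523897058823529,0.3210313580822
0.551470588235294,0.267077754521637
0.579044117647059,0.21233771654784
0.606617647058823,0.161590033259473
0.634191176470588,0.119919061206643
0.661764705882353,0.0920421892590521
0.689338235294118,0.0816541697336463
0.716911764705882,0.0908857331681393
0.744485294117647,0.119958096590997
0.772058823529412,0.167086774414375
0.799632352941176,0.228651738125358
0.827205882352941,0.299611920556661
0.854779411764706,0.374106210151418
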