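CCG00001
CCG00002
CCG00003
CCG00004
CCG00005
CCG00006
CCG00007
CCG00008
CCG00009
CCG00010
CCG00011
CCG00012
CCG00013
CCG00014
CCG00015
CCG00016
CCG00017
CCG00018
CCG00019
CCG00020
CCG00021
CCG00022
CCG00023
CCG00024
CCG00025
CCG00026
CCG00027
CCG00028
CCG00029
CCG00030
CCG00031
CCG00032
CCG00033
CCG00034
CCG00035
CCG00036
CCG00037
CCG00038
CCG00039
CCG00040
CCG00041
CCG00042
CCG00043
CCG00044
CCG00045
CCG00046
CCG00047
CCG00048
CCG00049
CCG00050
CCG00051
CCG00052
CCG00053
CCG00054
CCG00055
CCG00056
CCG00057
CCG00058
CCG00059
CCG00060
CCG00061
CCG00062
CCG00063
CCG00064
CCG00065
CCG00066
CCG00067
CCG00068
CCG00069
CCG00070
CCG00071
CCG00072
CCG00073
CCG00074
CCG00075
CCG00076
CCG00077
CCG00078
CCG00079
CCG00080
CCG00081
CCG00082
CCG00083
CCG00084
CCG00085
CCG00086
CCG00087
CCG00088
CCG00089
CCG00090
CCG00091
CCG00092
CCG00093
CCG00094
CCG00095
CCG00096
CCG00097
CCG00098
CCG00099
CCG00100
CCG00101
CCG00102
CCG00103
CCG00104
CCG00105
CCG00106
CCG00107
CCG00108
CCG00109
CCG00110
CCG00111
CCG00112
CCG00113
CCG00114
CCG00115
CCG00116
CCG00117
CCG00118
CCG00119
CCG00120
CCG00121
CCG00122
CCG00123
CCG00124
CCG00125
CCG00126
CCG00127
CCG00128
CCG00129
CCG00130
CCG00131
CCG00132
CCG00133
CCG00134
CCG00135
CCG00136
CCG00137
CCG00138
CCG00139
CCG00140
CCG00141
CCG00142
CCG00143
CCG00144
CCG00145
CCG00146
CCG00147
CCG00148
CCG00149
CCG00150
CCG00151
CCG00152
CCG00153
CCG00154
CCG00155
CCG00156
CCG00157
CCG00158
CCG00159
CCG00160
CCG00161
CCG00162
CCG00163
CCG00164
CCG00165
CCG00166
CCG00167
CCG00168
CCG00169
CCG00170
CCG00171
CCG00172
CCG00173
CCG00174
CCG00175
CCG00176
CCG00177
CCG00178
CCG00179
CCG00180
CCG00181
CCG00182
CCG00183
CCG00184
CCG00185
CCG00186
CCG00187
CCG00188
CCG00189
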