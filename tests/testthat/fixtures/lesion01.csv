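x,y,z,intensity
4,3,2,118
3,4,2,123
4,4,2,113
5,4,2,87
4,5,2,96
3,3,3,90
4,3,3,118
5,3,3,80
2,4,3,87
3,4,3,87
4,4,3,102
5,4,3,106
6,4,3,112
3,5,3,124
4,5,3,99
5,5,3,111
4,2,4,128
2,3,4,131
3,3,4,128
4,3,4,123
5,3,4,83
6,3,4,73
2,4,4,95
3,4,4,91
4,4,4,103
5,4,4,105
6,4,4,116
2,5,4,111
3,5,4,87
4,5,4,102
5,5,4,111
6,5,4,90
4,6,4,109
3,2,5,81
4,2,5,74
5,2,5,80
2,3,5,121
3,3,5,120
4,3,5,93
5,3,5,102
6,3,5,85
2,4,5,117
3,4,5,102
4,4,5,112
5,4,5,95
6,4,5,101
2,5,5,110
3,5,5,101
4,5,5,93
5,5,5,104
6,5,5,101
3,6,5,77
4,6,5,84
5,6,5,85
4,2,6,100
2,3,6,85
3,3,6,77
4,3,6,103
5,3,6,92
6,3,6,110
2,4,6,134
3,4,6,73
4,4,6,97
5,4,6,93
6,4,6,85
2,5,6,101
3,5,6,122
4,5,6,99
5,5,6,109
6,5,6,86
4,6,6,89
3,3,7,99
4,3,7,108
5,3,7,117
2,4,7,72
3,4,7,82
4,4,7,106
5,4,7,123
6,4,7,104
3,5,7,92
4,5,7,91
5,5,7,100
4,3,8,118
3,4,8,99
4,4,8,88
5,4,8,86
4,5,8,85
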