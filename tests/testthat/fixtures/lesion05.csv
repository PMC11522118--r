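x,y,z,intensity
4,3,2,76
3,4,2,82
4,4,2,81
5,4,2,80
3,5,2,89
4,5,2,91
5,5,2,91
3,6,2,102
4,6,2,107
5,6,2,107
4,7,2,120
3,2,3,80
4,2,3,84
5,2,3,90
3,3,3,90
4,3,3,90
5,3,3,89
2,4,3,92
3,4,3,91
4,4,3,89
5,4,3,88
6,4,3,91
2,5,3,87
3,5,3,89
4,5,3,90
5,5,3,91
6,5,3,96
2,6,3,88
3,6,3,94
4,6,3,98
5,6,3,101
6,6,3,106
3,7,3,106
4,7,3,109
5,7,3,109
3,8,3,115
4,8,3,113
5,8,3,107
3,2,4,98
4,2,4,104
5,2,4,104
3,3,4,110
4,3,4,110
5,3,4,102
2,4,4,108
3,4,4,109
4,4,4,106
5,4,4,99
6,4,4,94
2,5,4,100
3,5,4,101
4,5,4,100
5,5,4,97
6,5,4,96
2,6,4,94
3,6,4,97
4,6,4,99
5,6,4,100
6,6,4,100
3,7,4,97
4,7,4,101
5,7,4,102
3,8,4,96
4,8,4,97
5,8,4,94
3,2,5,107
4,2,5,115
5,2,5,109
3,3,5,119
4,3,5,120
5,3,5,107
2,4,5,112
3,4,5,118
4,4,5,117
5,4,5,105
6,4,5,92
2,5,5,106
3,5,5,110
4,5,5,111
5,5,5,104
6,5,5,94
2,6,5,96
3,6,5,102
4,6,5,106
5,6,5,104
6,6,5,95
3,7,5,93
4,7,5,99
5,7,5,99
3,8,5,82
4,8,5,86
5,8,5,86
4,3,6,115
3,4,6,111
4,4,6,114
5,4,6,103
3,5,6,108
4,5,6,113
5,5,6,106
3,6,6,104
4,6,6,111
5,6,6,107
4,7,6,103
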