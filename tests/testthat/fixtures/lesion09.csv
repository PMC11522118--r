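x,y,z,intensity
3,3,2,92
4,3,2,93
5,3,2,110
3,4,2,99
4,4,2,101
5,4,2,112
3,5,2,117
4,5,2,121
5,5,2,118
3,2,3,107
4,2,3,119
5,2,3,132
3,3,3,110
4,3,3,114
5,3,3,127
3,4,3,117
4,4,3,115
5,4,3,120
3,5,3,129
4,5,3,126
5,5,3,115
3,6,3,132
4,6,3,131
5,6,3,107
3,2,4,113
4,2,4,125
5,2,4,135
3,3,4,121
4,3,4,122
5,3,4,128
2,4,4,128
3,4,4,122
4,4,4,113
5,4,4,113
6,4,4,105
3,5,4,125
4,5,4,115
5,5,4,103
3,6,4,126
4,6,4,121
5,6,4,101
3,2,5,109
4,2,5,116
5,2,5,126
2,3,5,113
3,3,5,107
4,3,5,108
5,3,5,116
6,3,5,113
2,4,5,110
3,4,5,103
4,4,5,97
5,4,5,99
6,4,5,95
2,5,5,107
3,5,5,105
4,5,5,96
5,5,5,92
6,5,5,84
3,6,5,110
4,6,5,106
5,6,5,98
3,2,6,95
4,2,6,98
5,2,6,110
3,3,6,78
4,3,6,81
5,3,6,96
2,4,6,74
3,4,6,72
4,4,6,74
5,4,6,85
6,4,6,88
3,5,6,81
4,5,6,83
5,5,6,87
3,6,6,92
4,6,6,97
5,6,6,93
3,2,7,87
4,2,7,90
5,2,7,102
3,3,7,61
4,3,7,65
5,3,7,80
3,4,7,57
4,4,7,64
5,4,7,79
3,5,7,71
4,5,7,82
5,5,7,92
3,6,7,81
4,6,7,93
5,6,7,92
3,3,8,58
4,3,8,64
5,3,8,77
3,4,8,56
4,4,8,63
5,4,8,75
3,5,8,67
4,5,8,78
5,5,8,90
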