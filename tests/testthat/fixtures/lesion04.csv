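x,y,z,intensity
4,2,2,112
3,3,2,134
4,3,2,143
5,3,2,117
3,4,2,111
4,4,2,122
5,4,2,118
3,5,2,86
4,5,2,82
5,5,2,98
4,6,2,46
3,2,3,144
4,2,3,131
5,2,3,109
2,3,3,145
3,3,3,129
4,3,3,132
5,3,3,118
6,3,3,97
2,4,3,155
3,4,3,109
4,4,3,97
5,4,3,65
6,4,3,62
2,5,3,128
3,5,3,98
4,5,3,84
5,5,3,55
6,5,3,39
3,6,3,82
4,6,3,78
5,6,3,96
3,2,4,130
4,2,4,128
5,2,4,106
2,3,4,134
3,3,4,105
4,3,4,117
5,3,4,98
6,3,4,94
2,4,4,139
3,4,4,86
4,4,4,87
5,4,4,50
6,4,4,73
2,5,4,134
3,5,4,101
4,5,4,99
5,5,4,67
6,5,4,78
3,6,4,98
4,6,4,94
5,6,4,107
3,2,5,87
4,2,5,97
5,2,5,94
2,3,5,105
3,3,5,85
4,3,5,120
5,3,5,105
6,3,5,76
2,4,5,98
3,4,5,85
4,4,5,113
5,4,5,89
6,4,5,79
2,5,5,99
3,5,5,85
4,5,5,91
5,5,5,77
6,5,5,93
3,6,5,69
4,6,5,86
5,6,5,105
4,2,6,93
3,3,6,57
4,3,6,113
5,3,6,131
3,4,6,75
4,4,6,135
5,4,6,143
3,5,6,58
4,5,6,100
5,5,6,112
4,6,6,99
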