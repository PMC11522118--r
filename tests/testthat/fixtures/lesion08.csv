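x,y,z,intensity
4,3,2,135
3,4,2,44
4,4,2,49
5,4,2,102
4,5,2,123
4,2,3,199
3,3,3,126
4,3,3,126
5,3,3,78
2,4,3,-22
3,4,3,25
4,4,3,74
5,4,3,70
6,4,3,120
3,5,3,73
4,5,3,103
5,5,3,84
4,6,3,36
3,2,4,106
4,2,4,143
5,2,4,144
2,3,4,88
3,3,4,50
4,3,4,3
5,3,4,129
6,3,4,82
2,4,4,-1
3,4,4,67
4,4,4,118
5,4,4,144
6,4,4,162
2,5,4,26
3,5,4,105
4,5,4,141
5,5,4,112
6,5,4,56
3,6,4,152
4,6,4,105
5,6,4,67
4,2,5,93
3,3,5,39
4,3,5,60
5,3,5,131
2,4,5,61
3,4,5,115
4,4,5,197
5,4,5,147
6,4,5,79
3,5,5,101
4,5,5,148
5,5,5,99
4,6,5,112
4,3,6,108
3,4,6,151
4,4,6,223
5,4,6,162
4,5,6,133
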