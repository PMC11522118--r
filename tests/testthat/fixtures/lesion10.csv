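x,y,z,intensity
5,3,2,135
4,4,2,75
5,4,2,98
6,4,2,107
5,5,2,61
5,2,3,91
3,3,3,66
4,3,3,64
5,3,3,122
6,3,3,140
7,3,3,123
3,4,3,99
4,4,3,90
5,4,3,131
6,4,3,147
7,4,3,123
3,5,3,127
4,5,3,113
5,5,3,122
6,5,3,129
7,5,3,93
5,6,3,106
3,2,4,45
4,2,4,53
5,2,4,79
6,2,4,76
7,2,4,81
2,3,4,71
3,3,4,61
4,3,4,35
5,3,4,68
6,3,4,93
7,3,4,109
8,3,4,138
2,4,4,105
3,4,4,87
4,4,4,63
5,4,4,88
6,4,4,112
7,4,4,110
8,4,4,125
2,5,4,131
3,5,4,137
4,5,4,117
5,5,4,117
6,5,4,126
7,5,4,98
8,5,4,81
3,6,4,140
4,6,4,127
5,6,4,110
6,6,4,103
7,6,4,67
3,2,5,33
4,2,5,70
5,2,5,112
6,2,5,103
7,2,5,86
2,3,5,77
3,3,5,57
4,3,5,44
5,3,5,65
6,3,5,71
7,3,5,82
8,3,5,111
2,4,5,120
3,4,5,100
4,4,5,66
5,4,5,58
6,4,5,55
7,4,5,71
8,4,5,108
2,5,5,168
3,5,5,164
4,5,5,120
5,5,5,99
6,5,5,101
7,5,5,97
8,5,5,98
3,6,5,173
4,6,5,144
5,6,5,120
6,6,5,114
7,6,5,92
3,2,6,14
4,2,6,59
5,2,6,106
6,2,6,101
7,2,6,73
2,3,6,69
3,3,6,45
4,3,6,62
5,3,6,81
6,3,6,67
7,3,6,61
8,3,6,81
2,4,6,119
3,4,6,127
4,4,6,119
5,4,6,83
6,4,6,39
7,4,6,43
8,4,6,74
2,5,6,164
3,5,6,175
4,5,6,148
5,5,6,118
6,5,6,84
7,5,6,65
8,5,6,75
3,6,6,170
4,6,6,152
5,6,6,143
6,6,6,121
7,6,6,86
3,2,7,45
4,2,7,58
5,2,7,98
6,2,7,104
7,2,7,86
2,3,7,80
3,3,7,68
4,3,7,96
5,3,7,123
6,3,7,92
7,3,7,67
8,3,7,75
2,4,7,115
3,4,7,145
4,4,7,162
5,4,7,128
6,4,7,60
7,4,7,37
8,4,7,50
2,5,7,147
3,5,7,160
4,5,7,154
5,5,7,131
6,5,7,77
7,5,7,30
8,5,7,45
3,6,7,160
4,6,7,157
5,6,7,154
6,6,7,116
7,6,7,67
3,2,8,78
4,2,8,43
5,2,8,63
6,2,8,92
7,2,8,95
2,3,8,144
3,3,8,110
4,3,8,99
5,3,8,115
6,3,8,102
7,3,8,86
8,3,8,81
2,4,8,154
3,4,8,166
4,4,8,150
5,4,8,114
6,4,8,75
7,4,8,61
8,4,8,59
2,5,8,159
3,5,8,161
4,5,8,139
5,5,8,107
6,5,8,72
7,5,8,39
8,5,8,56
3,6,8,160
4,6,8,142
5,6,8,118
6,6,8,92
7,6,8,58
5,2,9,74
3,3,9,116
4,3,9,73
5,3,9,102
6,3,9,122
7,3,9,107
3,4,9,139
4,4,9,117
5,4,9,115
6,4,9,101
7,4,9,78
3,5,9,132
4,5,9,133
5,5,9,121
6,5,9,85
7,5,9,50
5,6,9,101
5,3,10,116
4,4,10,109
5,4,10,141
6,4,10,129
5,5,10,148
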