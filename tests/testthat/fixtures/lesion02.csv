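x,y,z,intensity
5,5,2,122
4,3,3,99
5,3,3,148
6,3,3,192
3,4,3,66
4,4,3,98
5,4,3,151
6,4,3,190
7,4,3,193
3,5,3,59
4,5,3,89
5,5,3,134
6,5,3,161
7,5,3,171
3,6,3,87
4,6,3,103
5,6,3,110
6,6,3,125
7,6,3,151
4,7,3,137
5,7,3,106
6,7,3,114
5,2,4,124
3,3,4,101
4,3,4,112
5,3,4,137
6,3,4,176
7,3,4,180
2,4,4,93
3,4,4,97
4,4,4,116
5,4,4,147
6,4,4,180
7,4,4,188
8,4,4,151
2,5,4,91
3,5,4,84
4,5,4,104
5,5,4,148
6,5,4,178
7,5,4,175
8,5,4,143
2,6,4,110
3,6,4,106
4,6,4,110
5,6,4,127
6,6,4,151
7,6,4,160
8,6,4,142
3,7,4,143
4,7,4,137
5,7,4,108
6,7,4,119
7,7,4,158
5,8,4,97
4,2,5,106
5,2,5,103
6,2,5,134
3,3,5,133
4,3,5,116
5,3,5,113
6,3,5,138
7,3,5,153
2,4,5,101
3,4,5,125
4,4,5,131
5,4,5,132
6,4,5,134
7,4,5,137
8,4,5,126
2,5,5,82
3,5,5,94
4,5,5,115
5,5,5,141
6,5,5,144
7,5,5,128
8,5,5,116
2,6,5,90
3,6,5,96
4,6,5,108
5,6,5,127
6,6,5,140
7,6,5,139
8,6,5,140
3,7,5,116
4,7,5,120
5,7,5,106
6,7,5,118
7,7,5,153
4,8,5,121
5,8,5,97
6,8,5,106
4,2,6,82
5,2,6,66
6,2,6,91
3,3,6,130
4,3,6,96
5,3,6,80
6,3,6,101
7,3,6,124
2,4,6,110
3,4,6,134
4,4,6,114
5,4,6,79
6,4,6,74
7,4,6,85
8,4,6,91
2,5,6,87
3,5,6,100
4,5,6,91
5,5,6,70
6,5,6,57
7,5,6,54
8,5,6,82
2,6,6,68
3,6,6,79
4,6,6,84
5,6,6,78
6,6,6,69
7,6,6,79
8,6,6,131
3,7,6,80
4,7,6,97
5,7,6,91
6,7,6,85
7,7,6,107
4,8,6,100
5,8,6,102
6,8,6,99
4,2,7,61
5,2,7,44
6,2,7,51
3,3,7,116
4,3,7,83
5,3,7,53
6,3,7,57
7,3,7,77
2,4,7,126
3,4,7,142
4,4,7,95
5,4,7,24
6,4,7,19
7,4,7,43
8,4,7,59
2,5,7,112
3,5,7,123
4,5,7,71
5,5,7,2
6,5,7,-5
7,5,7,19
8,5,7,56
2,6,7,92
3,6,7,95
4,6,7,68
5,6,7,26
6,6,7,13
7,6,7,42
8,6,7,98
3,7,7,88
4,7,7,94
5,7,7,80
6,7,7,51
7,7,7,56
4,8,7,112
5,8,7,113
6,8,7,78
5,2,8,47
3,3,8,116
4,3,8,77
5,3,8,43
6,3,8,32
7,3,8,35
2,4,8,160
3,4,8,147
4,4,8,88
5,4,8,19
6,4,8,10
7,4,8,25
8,4,8,26
2,5,8,152
3,5,8,146
4,5,8,84
5,5,8,8
6,5,8,9
7,5,8,41
8,5,8,51
2,6,8,146
3,6,8,129
4,6,8,85
5,6,8,36
6,6,8,34
7,6,8,73
8,6,8,97
3,7,8,115
4,7,8,104
5,7,8,85
6,7,8,65
7,7,8,79
5,8,8,111
4,3,9,86
5,3,9,66
6,3,9,50
3,4,9,131
4,4,9,96
5,4,9,69
6,4,9,53
7,4,9,49
3,5,9,131
4,5,9,107
5,5,9,79
6,5,9,70
7,5,9,84
3,6,9,131
4,6,9,110
5,6,9,97
6,6,9,98
7,6,9,119
4,7,9,104
5,7,9,98
6,7,9,102
5,5,10,145
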