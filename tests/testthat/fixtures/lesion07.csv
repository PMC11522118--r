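x,y,z,intensity
5,3,3,81
6,3,3,76
7,3,3,76
8,3,3,82
4,4,3,95
8,4,3,73
4,5,3,99
5,5,3,82
7,5,3,61
5,2,4,92
6,2,4,84
8,2,4,78
5,3,4,91
8,3,4,75
9,3,4,78
3,4,4,119
4,4,4,105
6,4,4,77
7,4,4,69
8,4,4,68
9,4,4,72
5,5,4,88
6,5,4,72
7,5,4,61
8,5,4,58
4,6,4,105
5,6,4,85
6,6,4,66
7,6,4,52
5,2,5,107
6,2,5,93
8,2,5,76
4,3,5,118
5,3,5,103
6,3,5,89
7,3,5,78
8,3,5,73
3,4,5,128
5,4,5,99
7,4,5,71
8,4,5,67
4,5,5,111
8,5,5,58
9,5,5,61
7,6,5,54
8,6,5,48
4,2,6,140
6,2,6,106
7,2,6,91
3,3,6,147
5,3,6,117
6,3,6,99
8,3,6,77
9,3,6,76
2,4,6,149
3,4,6,140
4,4,6,126
5,4,6,109
6,4,6,91
8,4,6,70
10,4,6,76
3,5,6,131
4,5,6,117
5,5,6,100
6,5,6,83
7,5,6,69
8,5,6,62
9,5,6,63
4,6,6,110
6,6,6,74
8,6,6,53
4,2,7,159
7,2,7,103
3,3,7,164
4,3,7,151
5,3,7,132
8,3,7,86
9,3,7,84
4,4,7,139
5,4,7,121
7,4,7,87
4,5,7,127
7,5,7,78
9,5,7,70
4,6,7,118
5,6,7,101
8,6,7,62
5,2,8,157
7,2,8,117
8,2,8,105
3,3,8,178
4,3,8,165
5,3,8,147
6,3,8,126
8,3,8,97
9,3,8,94
4,4,8,153
5,4,8,135
6,4,8,116
7,4,8,99
8,4,8,90
9,4,8,87
3,5,8,154
7,5,8,91
9,5,8,79
4,6,8,131
5,6,8,115
6,6,8,98
4,3,9,175
6,3,9,138
8,3,9,109
4,4,9,164
5,4,9,147
6,4,9,128
5,5,9,137
7,5,9,105
8,5,9,96
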