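x,y,z,intensity
5,4,2,64
4,3,3,62
5,3,3,62
6,3,3,51
3,4,3,55
4,4,3,59
5,4,3,51
6,4,3,34
7,4,3,14
4,5,3,71
5,5,3,56
6,5,3,32
4,2,4,62
5,2,4,83
6,2,4,87
3,3,4,37
4,3,4,52
5,3,4,58
6,3,4,55
7,3,4,42
3,4,4,54
4,4,4,60
5,4,4,55
6,4,4,44
7,4,4,30
3,5,4,85
4,5,4,83
5,5,4,68
6,5,4,47
7,5,4,29
4,6,4,114
5,6,4,87
6,6,4,53
3,2,5,38
4,2,5,67
5,2,5,81
6,2,5,79
7,2,5,66
2,3,5,29
3,3,5,53
4,3,5,68
5,3,5,71
6,3,5,64
7,3,5,51
8,3,5,33
2,4,5,65
3,4,5,81
4,4,5,86
5,4,5,79
6,4,5,67
7,4,5,54
8,4,5,38
2,5,5,107
3,5,5,119
4,5,5,117
5,5,5,101
6,5,5,80
7,5,5,63
8,5,5,49
3,6,5,160
4,6,5,151
5,6,5,123
6,6,5,90
7,6,5,67
3,2,6,76
4,2,6,94
5,2,6,85
6,2,6,59
7,2,6,31
2,3,6,75
3,3,6,101
4,3,6,108
5,3,6,92
6,3,6,65
7,3,6,40
8,3,6,19
2,4,6,114
3,4,6,133
4,4,6,133
5,4,6,113
6,4,6,86
7,4,6,63
8,4,6,45
2,5,6,154
3,5,6,168
4,5,6,164
5,5,6,141
6,5,6,112
7,5,6,88
8,5,6,71
3,6,6,201
4,6,6,193
5,6,6,165
6,6,6,129
7,6,6,101
3,2,7,121
4,2,7,123
5,2,7,89
6,2,7,35
7,2,7,-15
2,3,7,130
3,3,7,155
4,3,7,149
5,3,7,110
6,3,7,56
7,3,7,11
8,3,7,-15
2,4,7,169
3,4,7,189
4,4,7,180
5,4,7,141
6,4,7,91
7,4,7,53
8,4,7,31
2,5,7,200
3,5,7,216
4,5,7,208
5,5,7,174
6,5,7,129
7,5,7,93
8,5,7,73
3,6,7,235
4,6,7,229
5,6,7,196
6,6,7,151
7,6,7,115
4,2,8,137
5,2,8,87
6,2,8,14
3,3,8,187
4,3,8,173
5,3,8,118
6,3,8,45
7,3,8,-14
3,4,8,222
4,4,8,207
5,4,8,154
6,4,8,87
7,4,8,36
3,5,8,243
4,5,8,232
5,5,8,187
6,5,8,128
7,5,8,83
4,6,8,243
5,6,8,204
6,6,8,151
4,3,9,171
5,3,9,113
6,3,9,36
3,4,9,223
4,4,9,207
5,4,9,151
6,4,9,78
7,4,9,23
4,5,9,227
5,5,9,178
6,5,9,113
5,4,10,131
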