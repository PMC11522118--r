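x,y,z,intensity
4,6,2,29
4,3,3,123
3,4,3,3
4,4,3,-46
5,4,3,268
2,5,3,93
3,5,3,139
4,5,3,35
5,5,3,66
6,5,3,126
2,6,3,116
3,6,3,-9
4,6,3,123
5,6,3,106
6,6,3,118
2,7,3,116
3,7,3,63
4,7,3,271
5,7,3,81
6,7,3,-36
3,8,3,110
4,8,3,159
5,8,3,88
4,9,3,270
4,2,4,266
3,3,4,136
4,3,4,221
5,3,4,76
2,4,4,151
3,4,4,65
4,4,4,122
5,4,4,240
6,4,4,-103
2,5,4,111
3,5,4,-7
4,5,4,76
5,5,4,216
6,5,4,-81
2,6,4,181
3,6,4,329
4,6,4,113
5,6,4,154
6,6,4,17
2,7,4,-56
3,7,4,196
4,7,4,57
5,7,4,-4
6,7,4,65
2,8,4,79
3,8,4,130
4,8,4,71
5,8,4,29
6,8,4,79
3,9,4,11
4,9,4,107
5,9,4,178
4,10,4,265
4,2,5,121
3,3,5,182
4,3,5,227
5,3,5,49
2,4,5,20
3,4,5,166
4,4,5,104
5,4,5,147
6,4,5,-27
2,5,5,29
3,5,5,209
4,5,5,53
5,5,5,88
6,5,5,46
2,6,5,77
3,6,5,186
4,6,5,172
5,6,5,93
6,6,5,82
2,7,5,47
3,7,5,225
4,7,5,41
5,7,5,74
6,7,5,161
2,8,5,174
3,8,5,127
4,8,5,87
5,8,5,118
6,8,5,95
3,9,5,193
4,9,5,120
5,9,5,150
4,10,5,94
4,2,6,45
3,3,6,81
4,3,6,185
5,3,6,71
2,4,6,111
3,4,6,17
4,4,6,114
5,4,6,225
6,4,6,87
2,5,6,77
3,5,6,33
4,5,6,37
5,5,6,127
6,5,6,31
2,6,6,-62
3,6,6,-24
4,6,6,92
5,6,6,174
6,6,6,22
2,7,6,24
3,7,6,117
4,7,6,91
5,7,6,-17
6,7,6,167
2,8,6,128
3,8,6,-45
4,8,6,88
5,8,6,19
6,8,6,210
3,9,6,87
4,9,6,38
5,9,6,22
4,10,6,164
4,3,7,174
3,4,7,-31
4,4,7,142
5,4,7,146
2,5,7,-4
3,5,7,278
4,5,7,91
5,5,7,159
6,5,7,153
2,6,7,76
3,6,7,-26
4,6,7,194
5,6,7,106
6,6,7,73
2,7,7,124
3,7,7,85
4,7,7,56
5,7,7,15
6,7,7,140
3,8,7,151
4,8,7,117
5,8,7,81
4,9,7,134
4,6,8,93
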