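%%MatrixMarket matrix coordinate integer general
5 96 223
2 1 5
3 1 1
4 1 41
5 1 1
1 2 5
5 2 2
1 3 33
4 3 18
1 4 4
3 4 2
1 5 16
5 5 2
1 6 3
2 6 2
3 6 2
1 7 8
5 7 5
1 8 2
2 8 1
3 8 1
4 8 1
5 8 1
1 9 3
2 9 15
3 9 1
4 9 1
2 10 1
4 10 9
5 10 2
1 11 2
2 11 3
1 12 17
2 12 3
3 13 2
4 13 2
1 14 12
1 15 1
2 15 1
4 15 1
5 15 1
1 16 4
2 16 2
3 16 1
1 17 8
2 17 3
5 18 1
1 19 1
4 19 1
5 19 1
2 20 1
1 21 27
1 22 1
2 22 3
5 22 1
1 23 4
3 23 1
4 23 1
5 23 1
1 24 3
2 24 16
1 25 2
2 25 6
4 25 1
2 26 3
3 26 1
1 27 4
5 27 3
1 28 14
2 28 10
3 28 4
1 29 7
2 29 7
3 29 2
1 30 4
2 30 9
2 31 20
1 32 8
2 32 4
3 32 1
4 32 5
1 33 1
2 33 4
3 33 2
4 33 2
5 33 1
1 34 12
2 34 14
2 35 5
4 35 11
1 36 13
3 36 3
1 37 15
2 37 1
4 37 3
2 38 3
1 39 6
2 39 4
4 39 12
5 39 1
5 40 1
1 41 4
2 41 7
4 41 2
1 42 3
2 42 4
4 42 3
2 43 4
3 43 1
5 43 1
1 44 16
1 45 7
2 45 2
1 46 1
2 46 18
1 47 3
2 47 4
1 48 43
2 48 3
4 48 4
5 48 4
1 49 1
5 49 1
1 50 22
2 50 1
4 50 1
2 51 11
1 52 4
2 52 3
4 52 6
1 54 3
4 54 1
1 55 11
2 55 2
1 56 1
2 56 3
4 56 3
2 57 13
4 57 1
1 58 11
3 58 1
4 58 1
1 59 7
3 59 2
4 59 1
1 60 2
4 60 5
5 60 3
1 61 6
2 61 3
2 62 11
3 62 8
4 62 3
5 62 1
2 63 18
4 63 1
1 64 9
2 64 5
3 64 2
4 64 1
1 65 1
2 65 2
1 66 2
2 66 1
3 66 1
1 67 13
2 67 3
3 67 2
2 68 14
1 69 8
2 69 3
1 70 3
3 70 4
1 71 1
2 71 3
5 71 1
1 72 2
3 72 1
4 72 12
1 73 6
1 74 14
2 74 2
2 75 1
1 76 1
1 77 43
2 78 3
4 78 2
1 80 34
4 80 2
1 81 10
4 81 1
1 82 4
2 82 2
5 82 1
1 83 14
2 83 2
2 84 2
4 84 8
1 85 1
2 85 5
4 85 1
1 86 25
1 87 2
2 87 3
4 87 6
2 88 1
2 89 6
4 89 20
1 91 3
2 91 4
1 92 2
4 92 1
2 93 1
2 94 3
3 94 1
4 94 2
1 95 10
2 95 3
3 95 1
4 95 11
5 95 2
1 96 25
2 96 13
4 96 3
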