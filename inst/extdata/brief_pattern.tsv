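x1	y1	x2	y2
8	-4	2	4
3	-1	9	-1
13	0	8	14
-9	-2	-1	4
-2	-15	-15	8
-2	-11	-1	8
12	-3	-2	-11
3	-4	3	4
6	-4	3	-11
-5	-5	-15	0
1	-2	5	-5
-8	3	-5	9
-3	4	2	-5
10	4	1	2
4	1	-15	2
-2	1	4	9
-5	8	2	6
6	4	-6	-1
4	-6	-3	4
5	3	-5	-7
9	2	1	-1
-7	4	-1	-1
6	5	9	-3
4	9	-7	-5
-7	-9	0	4
7	6	-6	11
-4	1	-3	-1
1	1	0	1
-3	-3	-10	-2
-3	15	-8	1
-9	-9	1	-6
0	-3	-4	-13
-8	1	4	-3
0	7	9	-7
-1	7	-3	0
-1	-6	-3	0
-3	7	-3	-3
4	-7	0	-10
7	-2	-3	-8
0	-5	-3	8
-1	-7	1	-2
4	9	-6	3
1	6	-1	5
-11	10	5	-1
-9	4	3	0
1	-4	2	2
-2	-8	4	3
-5	-10	1	-2
2	-8	-6	7
3	4	11	1
-12	2	7	13
-9	-7	-4	-7
-4	-1	-7	13
1	-1	3	0
-1	9	-1	-8
2	-2	-3	-7
-4	8	-2	6
-7	-3	-2	-2
8	0	2	-6
-5	6	8	8
-9	13	6	0
4	-6	-7	0
-7	1	8	-6
-5	0	-6	-2
5	6	2	-11
0	7	5	-1
-15	0	4	0
1	3	-2	8
3	-8	9	7
5	-10	-4	4
0	2	15	-5
-13	2	-4	3
-5	14	-1	-3
-1	5	1	-10
-1	0	3	6
-8	0	0	-5
-6	-4	4	-3
-5	1	-8	6
-3	1	0	0
11	-5	7	0
-5	0	5	-3
-5	1	6	0
-9	-8	-5	-3
0	4	-3	-7
4	2	7	-10
1	8	4	-5
5	-5	-3	7
-2	5	-2	-10
-5	-7	-3	-2
-1	-2	12	-9
-3	2	10	1
8	-10	9	-4
-2	-7	1	11
15	-7	3	9
-1	-1	-2	4
9	4	2	-2
3	-3	-2	7
3	1	-2	6
8	-5	0	0
-4	-6	0	4
9	-12	-4	-2
-10	-5	-5	-4
-14	1	-4	9
5	-9	1	-4
6	0	-3	3
1	-1	13	-3
-3	-10	0	6
-13	-2	-7	9
8	2	9	-5
6	-4	2	-2
-2	3	-8	-2
1	-3	1	-2
10	4	15	-5
5	13	2	-7
-6	0	8	5
-13	-4	0	-9
4	-15	1	-2
-3	-2	2	2
-1	-12	-9	-9
5	-2	2	-10
-3	3	-1	-1
0	8	-4	4
6	-7	1	0
6	6	0	1
-4	-1	-6	-6
-8	5	7	-3
-7	-1	14	13
-11	-2	10	0
10	-2	4	1
15	6	-7	-4
2	-12	-11	-7
-2	8	-2	1
0	-4	8	-7
-1	-2	3	10
3	9	5	-4
1	9	-10	2
-1	5	5	2
9	-9	6	-10
4	1	6	0
-10	-12	3	0
-4	-2	-4	-1
-6	-12	-1	6
12	0	-1	6
0	-3	-11	-8
3	-9	7	-8
-1	0	0	1
4	-1	-2	1
-3	10	-13	6
-2	3	6	5
-4	10	-10	5
-3	-12	-12	2
14	2	7	5
-4	6	2	1
6	5	-4	2
-6	4	-3	3
2	-2	3	4
-1	7	9	-4
-5	3	-6	-3
5	-4	-12	4
-10	-8	-15	5
2	3	5	0
-7	3	8	-9
-4	-2	-8	4
-4	8	0	5
10	2	7	1
-9	0	4	3
-1	-8	4	-6
-8	4	-8	2
0	-8	7	-4
7	-3	-4	0
-2	-2	-5	-8
4	-5	-9	-3
-5	-14	-2	1
2	2	-6	-2
-6	-4	-8	-7
4	-2	-2	11
0	-3	5	-3
9	-2	-4	-7
2	9	-2	2
2	9	4	-7
-4	-5	1	0
2	-4	-2	5
-1	-4	6	0
-6	11	-7	-11
-14	4	-3	-2
2	-3	-10	-12
-2	1	-14	2
3	8	1	1
4	0	0	1
5	-3	-3	-5
-6	2	10	-6
-1	-6	6	-2
1	2	-7	-1
-1	4	-8	-7
5	-4	-4	1
-2	12	2	1
6	0	0	-7
-14	-7	1	-6
4	4	1	-1
-8	-2	-3	4
8	3	-7	10
6	1	-14	-6
0	5	-7	15
-15	-1	-2	-4
-2	5	-5	-13
1	0	0	4
0	5	-12	-7
2	-2	6	-6
4	-4	-7	-2
0	-8	-5	-8
6	4	-6	3
-2	-7	3	-2
5	-1	7	-3
1	2	2	1
0	-1	8	6
-4	9	1	-4
1	-1	1	-6
-5	8	6	-5
-6	11	12	-5
-8	15	1	1
0	9	-1	9
-1	3	-6	1
7	-1	8	15
6	-2	1	-3
14	-15	1	1
1	-10	1	1
8	3	7	-6
-1	1	2	-4
9	-4	-10	2
4	6	-6	-2
-8	5	2	6
4	-4	1	-12
3	6	-5	-13
-9	-7	8	0
-8	3	-14	-2
7	-2	8	11
-7	-7	-6	3
5	7	8	7
6	1	-6	-5
3	10	11	-12
-5	9	-7	-10
4	11	12	3
4	3	0	-15
5	-2	6	-4
-10	8	1	15
6	7	5	-4
-2	7	7	4
-6	10	-8	-3
14	3	6	2
-6	-4	1	-15
-5	5	-2	-2
5	-3	4	-9
-8	-10	1	-1
9	0	8	12
-3	2	-5	5
-7	-6	2	1
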