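from_class,to_class,category,attributable
1,2,5,TRUE
1,3,5,TRUE
1,4,6,FALSE
1,5,6,FALSE
1,6,6,FALSE
1,7,6,FALSE
1,8,6,FALSE
1,9,6,FALSE
1,10,6,FALSE
1,11,6,FALSE
1,12,6,FALSE
1,13,6,FALSE
1,14,6,FALSE
1,15,6,FALSE
1,16,6,FALSE
1,17,6,FALSE
1,18,6,FALSE
1,19,6,FALSE
1,20,6,FALSE
2,1,5,TRUE
2,3,5,TRUE
2,4,6,FALSE
2,5,6,FALSE
2,6,6,FALSE
2,7,6,FALSE
2,8,6,FALSE
2,9,6,FALSE
2,10,6,FALSE
2,11,6,FALSE
2,12,6,FALSE
2,13,6,FALSE
2,14,6,FALSE
2,15,6,FALSE
2,16,6,FALSE
2,17,6,FALSE
2,18,6,FALSE
2,19,6,FALSE
2,20,6,FALSE
3,1,5,TRUE
3,2,5,TRUE
3,4,6,FALSE
3,5,6,FALSE
3,6,6,FALSE
3,7,6,FALSE
3,8,6,FALSE
3,9,6,FALSE
3,10,6,FALSE
3,11,6,FALSE
3,12,6,FALSE
3,13,6,FALSE
3,14,6,FALSE
3,15,6,FALSE
3,16,6,FALSE
3,17,6,FALSE
3,18,6,FALSE
3,19,6,FALSE
3,20,6,FALSE
4,1,2,TRUE
4,2,2,TRUE
4,3,3,FALSE
4,5,6,FALSE
4,6,6,FALSE
4,7,6,FALSE
4,8,6,FALSE
4,9,6,FALSE
4,10,6,FALSE
4,11,6,FALSE
4,12,6,FALSE
4,13,6,FALSE
4,14,6,FALSE
4,15,6,FALSE
4,16,6,FALSE
4,17,6,FALSE
4,18,6,FALSE
4,19,6,FALSE
4,20,6,FALSE
5,1,2,TRUE
5,2,2,TRUE
5,3,3,FALSE
5,4,4,FALSE
5,6,1,FALSE
5,7,1,FALSE
5,8,1,FALSE
5,9,1,FALSE
5,10,1,FALSE
5,11,1,FALSE
5,12,1,FALSE
5,13,1,FALSE
5,14,1,FALSE
5,15,1,FALSE
5,16,1,FALSE
5,17,1,FALSE
5,18,1,FALSE
5,19,1,FALSE
5,20,1,FALSE
6,1,2,TRUE
6,2,2,TRUE
6,3,3,FALSE
6,4,4,FALSE
6,5,1,FALSE
6,7,1,FALSE
6,8,1,FALSE
6,9,1,FALSE
6,10,1,FALSE
6,11,1,FALSE
6,12,1,FALSE
6,13,1,FALSE
6,14,1,FALSE
6,15,1,FALSE
6,16,1,FALSE
6,17,1,FALSE
6,18,1,FALSE
6,19,1,FALSE
6,20,1,FALSE
7,1,2,TRUE
7,2,2,TRUE
7,3,3,FALSE
7,4,4,FALSE
7,5,1,FALSE
7,6,1,FALSE
7,8,1,FALSE
7,9,1,FALSE
7,10,1,FALSE
7,11,1,FALSE
7,12,1,FALSE
7,13,1,FALSE
7,14,1,FALSE
7,15,1,FALSE
7,16,1,FALSE
7,17,1,FALSE
7,18,1,FALSE
7,19,1,FALSE
7,20,1,FALSE
8,1,2,TRUE
8,2,2,TRUE
8,3,3,FALSE
8,4,4,FALSE
8,5,1,FALSE
8,6,1,FALSE
8,7,1,FALSE
8,9,1,FALSE
8,10,1,FALSE
8,11,1,FALSE
8,12,1,FALSE
8,13,1,FALSE
8,14,1,FALSE
8,15,1,FALSE
8,16,1,FALSE
8,17,1,FALSE
8,18,1,FALSE
8,19,1,FALSE
8,20,1,FALSE
9,1,2,TRUE
9,2,2,TRUE
9,3,3,FALSE
9,4,4,FALSE
9,5,1,FALSE
9,6,1,FALSE
9,7,1,FALSE
9,8,1,FALSE
9,10,1,FALSE
9,11,1,FALSE
9,12,1,FALSE
9,13,1,FALSE
9,14,1,FALSE
9,15,1,FALSE
9,16,1,FALSE
9,17,1,FALSE
9,18,1,FALSE
9,19,1,FALSE
9,20,1,FALSE
10,1,2,TRUE
10,2,2,TRUE
10,3,3,FALSE
10,4,4,FALSE
10,5,1,FALSE
10,6,1,FALSE
10,7,1,FALSE
10,8,1,FALSE
10,9,1,FALSE
10,11,1,FALSE
10,12,1,FALSE
10,13,1,FALSE
10,14,1,FALSE
10,15,1,FALSE
10,16,1,FALSE
10,17,1,FALSE
10,18,1,FALSE
10,19,1,FALSE
10,20,1,FALSE
11,1,2,TRUE
11,2,2,TRUE
11,3,3,FALSE
11,4,4,FALSE
11,5,1,FALSE
11,6,1,FALSE
11,7,1,FALSE
11,8,1,FALSE
11,9,1,FALSE
11,10,1,FALSE
11,12,1,FALSE
11,13,1,FALSE
11,14,1,FALSE
11,15,1,FALSE
11,16,1,FALSE
11,17,1,FALSE
11,18,1,FALSE
11,19,1,FALSE
11,20,1,FALSE
12,1,2,TRUE
12,2,2,TRUE
12,3,3,FALSE
12,4,4,FALSE
12,5,1,FALSE
12,6,1,FALSE
12,7,1,FALSE
12,8,1,FALSE
12,9,1,FALSE
12,10,1,FALSE
12,11,1,FALSE
12,13,1,FALSE
12,14,1,FALSE
12,15,1,FALSE
12,16,1,FALSE
12,17,1,FALSE
12,18,1,FALSE
12,19,1,FALSE
12,20,1,FALSE
13,1,2,TRUE
13,2,2,TRUE
13,3,3,FALSE
13,4,4,FALSE
13,5,1,FALSE
13,6,1,FALSE
13,7,1,FALSE
13,8,1,FALSE
13,9,1,FALSE
13,10,1,FALSE
13,11,1,FALSE
13,12,1,FALSE
13,14,1,FALSE
13,15,1,FALSE
13,16,1,FALSE
13,17,1,FALSE
13,18,1,FALSE
13,19,1,FALSE
13,20,1,FALSE
14,1,2,TRUE
14,2,2,TRUE
14,3,3,FALSE
14,4,4,FALSE
14,5,1,FALSE
14,6,1,FALSE
14,7,1,FALSE
14,8,1,FALSE
14,9,1,FALSE
14,10,1,FALSE
14,11,1,FALSE
14,12,1,FALSE
14,13,1,FALSE
14,15,1,FALSE
14,16,1,FALSE
14,17,1,FALSE
14,18,1,FALSE
14,19,1,FALSE
14,20,1,FALSE
15,1,2,TRUE
15,2,2,TRUE
15,3,3,FALSE
15,4,4,FALSE
15,5,1,FALSE
15,6,1,FALSE
15,7,1,FALSE
15,8,1,FALSE
15,9,1,FALSE
15,10,1,FALSE
15,11,1,FALSE
15,12,1,FALSE
15,13,1,FALSE
15,14,1,FALSE
15,16,1,FALSE
15,17,1,FALSE
15,18,1,FALSE
15,19,1,FALSE
15,20,1,FALSE
16,1,2,TRUE
16,2,2,TRUE
16,3,3,FALSE
16,4,4,FALSE
16,5,1,FALSE
16,6,1,FALSE
16,7,1,FALSE
16,8,1,FALSE
16,9,1,FALSE
16,10,1,FALSE
16,11,1,FALSE
16,12,1,FALSE
16,13,1,FALSE
16,14,1,FALSE
16,15,1,FALSE
16,17,1,FALSE
16,18,1,FALSE
16,19,1,FALSE
16,20,1,FALSE
17,1,2,TRUE
17,2,2,TRUE
17,3,3,FALSE
17,4,4,FALSE
17,5,1,FALSE
17,6,1,FALSE
17,7,1,FALSE
17,8,1,FALSE
17,9,1,FALSE
17,10,1,FALSE
17,11,1,FALSE
17,12,1,FALSE
17,13,1,FALSE
17,14,1,FALSE
17,15,1,FALSE
17,16,1,FALSE
17,18,1,FALSE
17,19,1,FALSE
17,20,1,FALSE
18,1,2,TRUE
18,2,2,TRUE
18,3,3,FALSE
18,4,4,FALSE
18,5,1,FALSE
18,6,1,FALSE
18,7,1,FALSE
18,8,1,FALSE
18,9,1,FALSE
18,10,1,FALSE
18,11,1,FALSE
18,12,1,FALSE
18,13,1,FALSE
18,14,1,FALSE
18,15,1,FALSE
18,16,1,FALSE
18,17,1,FALSE
18,19,1,FALSE
18,20,1,FALSE
19,1,2,TRUE
19,2,2,TRUE
19,3,3,FALSE
19,4,4,FALSE
19,5,1,FALSE
19,6,1,FALSE
19,7,1,FALSE
19,8,1,FALSE
19,9,1,FALSE
19,10,1,FALSE
19,11,1,FALSE
19,12,1,FALSE
19,13,1,FALSE
19,14,1,FALSE
19,15,1,FALSE
19,16,1,FALSE
19,17,1,FALSE
19,18,1,FALSE
19,20,1,FALSE
20,1,2,TRUE
20,2,2,TRUE
20,3,3,FALSE
20,4,4,FALSE
20,5,1,FALSE
20,6,1,FALSE
20,7,1,FALSE
20,8,1,FALSE
20,9,1,FALSE
20,10,1,FALSE
20,11,1,FALSE
20,12,1,FALSE
20,13,1,FALSE
20,14,1,FALSE
20,15,1,FALSE
20,16,1,FALSE
20,17,1,FALSE
20,18,1,FALSE
20,19,1,FALSE
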