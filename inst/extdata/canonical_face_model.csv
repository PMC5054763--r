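index,region,x_mm,y_mm,z_mm
0,jawline,-64,-20,45
1,jawline,-62,-5,43
2,jawline,-59,11,39
3,jawline,-54,26,33
4,jawline,-47,40,26
5,jawline,-38,52,19
6,jawline,-27,62,13
7,jawline,-14,69,8
8,jawline,0,72,5
9,jawline,14,69,8
10,jawline,27,62,13
11,jawline,38,52,19
12,jawline,47,40,26
13,jawline,54,26,33
14,jawline,59,11,39
15,jawline,62,-5,43
16,jawline,64,-20,45
17,eyebrow_right,-48,-12,0
18,eyebrow_right,-41,-16,-4
19,eyebrow_right,-32,-18,-6
20,eyebrow_right,-22,-17,-7
21,eyebrow_right,-12,-14,-6
22,eyebrow_left,12,-14,-6
23,eyebrow_left,22,-17,-7
24,eyebrow_left,32,-18,-6
25,eyebrow_left,41,-16,-4
26,eyebrow_left,48,-12,0
27,nose,0,-8,-10
28,nose,0,4,-15
29,nose,0,14,-20
30,nose,0,22,-24
31,nose,-13,29,-11
32,nose,-7,31,-14
33,nose,0,32,-17
34,nose,7,31,-14
35,nose,13,29,-11
36,eye_right,-46.5,0,0
37,eye_right,-37.5,-4,-1
38,eye_right,-27.5,-4,-1
39,eye_right,-18.5,0,0
40,eye_right,-27.5,4,1
41,eye_right,-37.5,4,1
42,eye_left,18.5,0,0
43,eye_left,27.5,-4,-1
44,eye_left,37.5,-4,-1
45,eye_left,46.5,0,0
46,eye_left,37.5,4,1
47,eye_left,27.5,4,1
48,lips,-24,48,-2
49,lips,-16,43,-6
50,lips,-7,41,-8
51,lips,0,40,-9
52,lips,7,41,-8
53,lips,16,43,-6
54,lips,24,48,-2
55,lips,16,54,-5
56,lips,8,56,-7
57,lips,0,57,-8
58,lips,-8,56,-7
59,lips,-16,54,-5
60,lips,-19,48,-4
61,lips,-7,45,-7
62,lips,0,45,-8
63,lips,7,45,-7
64,lips,19,48,-4
65,lips,7,50,-7
66,lips,0,51,-8
67,lips,-7,50,-7
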