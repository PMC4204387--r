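run,sensitivity,specificity,accuracy
1,100,86,87.4
2,76.9,92.1,90.6
3,100,91.2,92.1
4,84.6,91.2,90.6
5,76.9,88.6,87.4
6,92.3,87.7,88.2
7,100,87.7,89
8,100,88.6,89.8
9,100,87.7,89
10,100,89.5,90.6
11,69.2,89.5,87.4
12,76.9,90.4,89
13,92.3,89.5,89.8
14,92.3,90.4,90.6
15,76.9,88.6,87.4
16,76.9,94.7,92.9
17,84.6,89.5,89
18,100,87.7,89
19,92.3,87.7,88.2
20,84.6,87.7,87.4
21,92.3,90.4,90.6
22,100,91.2,92.1
23,100,85.1,86.6
24,100,86.8,88.2
25,46.2,93,88.2
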