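aa	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
A	NA	0.5951	0.4732	0.3594	0.4667	0.5951	0.4113	0.8258	0.6079	0.4381	0.4117	0.5032	0.4869	0.4381	0.8093	0.7898	0.9034	0.4569	0.5421	0.5082
R	0.4869	NA	0.7898	0.5826	0.2886	0.92	0.6772	0.5916	0.8093	0.2729	0.2584	0.8445	0.2997	0.2729	0.4767	0.6182	0.5421	0.2832	0.33	0.3114
N	0.3871	0.6462	NA	0.7391	0.2365	0.6462	0.8637	0.4667	0.6321	0.2246	0.2136	0.7734	0.245	0.2246	0.3794	0.4869	0.4291	0.2325	0.268	0.2538
D	0.2941	0.4767	0.6047	NA	0.1879	0.4767	0.7066	0.3501	0.4667	0.1796	0.1718	0.5662	0.1939	0.1796	0.2886	0.3644	0.3237	0.1851	0.2101	0.2001
C	0.5704	0.3527	0.2891	0.2297	NA	0.3527	0.2568	0.4732	0.3594	0.7734	0.7227	0.3047	0.9669	0.7734	0.5826	0.4544	0.5137	0.8093	0.8637	0.9241
Q	0.4869	0.92	0.7898	0.5826	0.2886	NA	0.6772	0.5916	0.8093	0.2729	0.2584	0.8445	0.2997	0.2729	0.4767	0.6182	0.5421	0.2832	0.33	0.3114
E	0.3366	0.554	0.7066	0.8637	0.2101	0.554	NA	0.4033	0.5421	0.2001	0.1909	0.6608	0.2172	0.2001	0.33	0.4203	0.3718	0.2067	0.2365	0.2246
G	0.6757	0.7231	0.5704	0.4279	0.3871	0.7231	0.4929	NA	0.7391	0.3644	0.3433	0.6079	0.4033	0.3644	0.6608	0.9669	0.7561	0.3794	0.4474	0.4203
H	0.4974	0.9892	0.7725	0.5704	0.2941	0.9892	0.6626	0.6047	NA	0.278	0.2631	0.8258	0.3055	0.278	0.4869	0.6321	0.554	0.2886	0.3366	0.3174
I	0.5355	0.3336	0.2746	0.2195	0.9452	0.3336	0.2446	0.4453	0.3398	NA	0.7734	0.2891	0.9034	0.92	0.5468	0.4279	0.4829	0.9669	0.8076	0.8637
L	0.5032	0.3159	0.2611	0.21	0.8833	0.3159	0.2333	0.4195	0.3216	0.9452	NA	0.2746	0.8445	0.9452	0.5137	0.4034	0.4544	0.9034	0.7556	0.8076
K	0.4117	0.691	0.9452	0.6921	0.2493	0.691	0.8076	0.4974	0.6757	0.2365	0.2246	NA	0.2584	0.2365	0.4033	0.5192	0.4569	0.245	0.2832	0.268
M	0.5951	0.3663	0.2994	0.237	0.7911	0.3663	0.2655	0.4929	0.3733	0.7392	0.691	0.3159	NA	0.7392	0.6079	0.4732	0.5355	0.7734	0.9034	0.9669
F	0.5355	0.3336	0.2746	0.2195	0.9452	0.3336	0.2446	0.4453	0.3398	0.92	0.7734	0.2891	0.9034	NA	0.5468	0.4279	0.4829	0.9669	0.8076	0.8637
P	0.9892	0.5826	0.4637	0.3527	0.4767	0.5826	0.4034	0.8076	0.5951	0.4474	0.4203	0.4929	0.4974	0.4474	NA	0.7725	0.8833	0.4667	0.554	0.5192
S	0.6462	0.7556	0.5951	0.4453	0.3718	0.7556	0.5137	0.7911	0.7725	0.3501	0.33	0.6346	0.3871	0.3501	0.6321	NA	0.7227	0.3644	0.4291	0.4033
T	0.7392	0.6626	0.5245	0.3956	0.4203	0.6626	0.4544	0.9241	0.6772	0.3951	0.3718	0.5585	0.4381	0.3951	0.7227	0.8833	NA	0.4117	0.4869	0.4569
W	0.5585	0.3462	0.2841	0.2262	0.9892	0.3462	0.2526	0.4637	0.3527	0.7911	0.7392	0.2994	0.9452	0.7911	0.5704	0.4453	0.5032	NA	0.8445	0.9034
Y	0.6626	0.4034	0.3275	0.2568	0.7066	0.4034	0.2891	0.5468	0.4113	0.6608	0.6182	0.3462	0.7392	0.6608	0.6772	0.5245	0.5951	0.691	NA	0.7734
V	0.6211	0.3806	0.3102	0.2446	0.7561	0.3806	0.2746	0.5137	0.388	0.7066	0.6608	0.3275	0.7911	0.7066	0.6346	0.4929	0.5585	0.7392	0.9452	NA
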